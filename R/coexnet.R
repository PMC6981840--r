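#' Pearson correlation matrix for one diagnostic state
#'
#' Pairwise Pearson correlations between probes over the samples of one
#' state. Probes with zero variance have undefined correlations; their rows
#' and columns are set to 0 (diagonal stays 1) and the probes are flagged.
#'
#' @param x an `ExpressionMatrix` restricted to one state's samples (>= 3
#'   samples, >= 2 probes), or a plain probes-by-samples numeric matrix.
#' @param state state label attached to the result.
#' @return A `CorrelationMatrix`: list with `r` (symmetric matrix, unit
#'   diagonal), `state`, `zero_variance` (character vector of flagged
#'   probes).
#' @export
correlation_matrix <- function(x, state = NA_character_) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (nrow(v) < 2) stop("need >= 2 probes")
  if (ncol(v) < 3) stop("need >= 3 samples per state for Pearson correlation")
  sds <- apply(v, 1, stats::sd)
  zero <- rownames(v)[sds == 0]
  r <- suppressWarnings(stats::cor(t(v)))
  if (length(zero)) {
    r[zero, ] <- 0
    r[, zero] <- 0
  }
  diag(r) <- 1
  structure(list(r = r, state = state, zero_variance = zero),
            class = "CorrelationMatrix")
}

#' Threshold a correlation matrix into a signed network
#'
#' Keeps edges with `r > T` (positive network) or `r < -T` (negative
#' network); inequalities are strict, so boundary correlations are
#' excluded. All probes remain as nodes even when isolated, which keeps the
#' node set identical across states -- a requirement of the downstream
#' rewiring and consensus comparisons.
#'
#' @param corr a [correlation_matrix()].
#' @param threshold nonnegative correlation threshold T.
#' @param sign `"positive"` or `"negative"`.
#' @return A `SignedNetwork`: list with `nodes`, `edges` (data.frame
#'   `source, target, weight` with `source < target` lexicographically),
#'   `sign`, `threshold`, `state`.
#' @export
threshold_network <- function(corr, threshold,
                              sign = c("positive", "negative")) {
  stopifnot(inherits(corr, "CorrelationMatrix"))
  sign <- match.arg(sign)
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be nonnegative")
  r <- corr$r
  keep <- if (sign == "positive") r > threshold else r < -threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  nodes <- rownames(r)
  if (nrow(idx)) {
    a <- nodes[idx[, 1]]; b <- nodes[idx[, 2]]
    swap <- a > b
    edges <- data.frame(source = ifelse(swap, b, a),
                        target = ifelse(swap, a, b),
                        weight = r[idx], stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  signed_network(nodes, edges, sign, threshold, corr$state)
}

signed_network <- function(nodes, edges, sign, threshold, state) {
  structure(list(nodes = nodes, edges = edges, sign = sign,
                 threshold = threshold, state = state),
            class = "SignedNetwork")
}

#' @export
print.SignedNetwork <- function(x, ...) {
  cat(sprintf("SignedNetwork [%s, T = %s, state %s]: %d nodes, %d edges\n",
              x$sign, format(x$threshold), x$state, length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Build the per-state signed co-expression networks
#'
#' Splits the samples by diagnosis, computes one Pearson correlation matrix
#' per state, and thresholds each into positive and negative networks at
#' every requested threshold: with the default thresholds `c(0.1, 0.3)`
#' that is six networks per threshold level (3 states x 2 signs). All
#' networks share the full retained probe set as nodes.
#'
#' @param dataset a `FilteredDataset` or a linear-scale `ExpressionMatrix`
#'   (per-state Pearson correlations are computed on the values as given).
#' @param labels sample labels; taken from the dataset when omitted.
#' @param thresholds numeric vector of nonnegative thresholds.
#' @return A `StateNetworks` object: list with `networks` (nested list
#'   indexed `[[threshold]][[sign]][[state]]`), `correlations` (per-state
#'   `CorrelationMatrix`), `states`, `thresholds`.
#' @export
build_state_networks <- function(dataset, labels = NULL,
                                 thresholds = c(0.1, 0.3)) {
  if (inherits(dataset, "FilteredDataset")) {
    x <- dataset$data
    if (is.null(labels)) labels <- dataset$labels
  } else x <- dataset
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(labels)) stop("labels are required")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(x$values))
    stop("labels must be aligned with the samples")
  small <- names(which(table(labels) < 3))
  if (length(small))
    stop("state(s) with < 3 samples: ", paste(small, collapse = ", "))
  if (any(thresholds < 0)) stop("thresholds must be nonnegative")
  states <- levels(labels)

  correlations <- lapply(states, function(s)
    correlation_matrix(x$values[, labels == s, drop = FALSE], state = s))
  names(correlations) <- states

  networks <- list()
  for (T in thresholds) {
    tl <- format(T)
    networks[[tl]] <- list()
    for (sgn in c("positive", "negative")) {
      networks[[tl]][[sgn]] <- lapply(correlations, threshold_network,
                                      threshold = T, sign = sgn)
    }
  }
  structure(list(networks = networks, correlations = correlations,
                 states = states, thresholds = thresholds),
            class = "StateNetworks")
}

#' Export a signed network as an edge table
#'
#' @param network a `SignedNetwork`.
#' @param path optional TSV output path; when omitted the table is only
#'   returned.
#' @return data.frame `source, target, weight, sign, state, threshold`
#'   (invisibly when written to file).
#' @export
export_edge_table <- function(network, path = NULL) {
  stopifnot(inherits(network, "SignedNetwork"))
  tab <- network$edges
  n <- nrow(tab)
  tab$sign <- rep(network$sign, n)
  tab$state <- rep(network$state, n)
  tab$threshold <- rep(network$threshold, n)
  if (!is.null(path)) {
    tryCatch(data.table::fwrite(tab, path, sep = "\t", quote = FALSE),
             error = function(e)
               stop("writing edge table ", path, ": ", conditionMessage(e)))
    return(invisible(tab))
  }
  tab
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  g <- igraph::set_graph_attr(g, "sign", network$sign)
  g <- igraph::set_graph_attr(g, "state", as.character(network$state))
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  g
}

#' Export / import a signed network as GraphML
#'
#' Nodes, edge weights and the network-level attributes (sign, state,
#' threshold) round-trip through the file.
#'
#' @param network a `SignedNetwork`.
#' @param path GraphML file path.
#' @return `export_graphml` invisibly returns `path`; `import_graphml`
#'   returns the reconstructed `SignedNetwork`.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "SignedNetwork"))
  tryCatch(igraph::write_graph(as_igraph(network), path, format = "graphml"),
           error = function(e)
             stop("writing GraphML ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  w <- igraph::edge_attr(g, "weight")
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    edges <- data.frame(source = ifelse(swap, el[, 2], el[, 1]),
                        target = ifelse(swap, el[, 1], el[, 2]),
                        weight = if (is.null(w)) rep(NA_real_, nrow(el)) else w,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  signed_network(nodes, edges,
                 sign = igraph::graph_attr(g, "sign"),
                 threshold = igraph::graph_attr(g, "threshold"),
                 state = igraph::graph_attr(g, "state"))
}

#' Export a signed network in SIF format for Cytoscape
#'
#' Edges are written as `source <tab> pos|neg <tab> target`; isolated nodes
#' appear as single-column rows so the full node set survives import.
#'
#' @param network a `SignedNetwork`.
#' @param path SIF file path.
#' @return invisibly, `path`.
#' @export
export_sif <- function(network, path) {
  stopifnot(inherits(network, "SignedNetwork"))
  itype <- if (network$sign == "positive") "pos" else "neg"
  e <- network$edges
  lines <- if (nrow(e)) paste(e$source, itype, e$target, sep = "\t")
           else character(0)
  isolated <- setdiff(network$nodes, unique(c(e$source, e$target)))
  tryCatch(writeLines(c(lines, isolated), path),
           error = function(e2)
             stop("writing SIF ", path, ": ", conditionMessage(e2)))
  invisible(path)
}
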