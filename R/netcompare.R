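#' Per-node rewiring scores across condition networks
#'
#' Quantifies how much each node's connections change between the per-state
#' networks. For node v with adjacency vector `a_s(v)` in state s (entries
#' 0/1 in binary mode, |r| in weighted mode) and entrywise centroid
#' `c(v) = mean_s a_s(v)`, the raw score is
#' `sum_s || a_s(v) - c(v) ||^2` -- the variance of the node's connectivity
#' around its across-state centroid, summed over adjacency slots. The score
#' is 0 iff the node's adjacency is identical in every state, decomposes
#' additively over adjacency slots, and is invariant to the order of the
#' states. A slot whose edge is present in exactly 1 or exactly 2 of 3
#' states contributes exactly 2/3.
#'
#' @param networks list of `SignedNetwork`s (one per state) on an identical
#'   node set, e.g. `nets$networks[["0.1"]][["positive"]]` from
#'   [build_state_networks()].
#' @param mode `"binary"` (edge presence, default -- the thresholded edge
#'   tables are the comparison input) or `"weighted"` (absolute Pearson r).
#' @param variant `"raw"` (default), `"degree"` (raw score divided by the
#'   node's mean degree across states) or `"unsquared"` (sum of Euclidean
#'   distances to the centroid instead of squared distances).
#' @return A `RewiringTable` data.frame: `node`, `score`, `rank` (descending
#'   score, ties broken lexicographically by node ID), and one
#'   `degree_<state>` column per network.
#' @export
rewiring_scores <- function(networks, mode = c("binary", "weighted"),
                            variant = c("raw", "degree", "unsquared")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (!length(networks)) stop("need at least one network")
  stopifnot(all(vapply(networks, inherits, logical(1), "SignedNetwork")))
  nodes <- networks[[1]]$nodes
  for (nw in networks[-1])
    if (!identical(sort(nw$nodes), sort(nodes)))
      stop("networks must share an identical node set")
  if (length(networks) == 1)
    warning("a single network has no rewiring; all scores are 0")
  states <- vapply(networks, function(nw) as.character(nw$state), character(1))
  if (anyDuplicated(states)) states <- make.unique(states)

  adj <- lapply(networks, adjacency_matrix, nodes = nodes, mode = mode)
  C <- Reduce(`+`, adj) / length(adj)
  if (variant == "unsquared") {
    score <- Reduce(`+`, lapply(adj, function(A)
      sqrt(rowSums((A - C)^2))))
  } else {
    score <- Reduce(`+`, lapply(adj, function(A) rowSums((A - C)^2)))
  }
  degrees <- vapply(networks, function(nw) {
    A <- adjacency_matrix(nw, nodes, "binary")
    rowSums(A)
  }, numeric(length(nodes)))
  if (is.null(dim(degrees))) degrees <- matrix(degrees, nrow = length(nodes))
  colnames(degrees) <- paste0("degree_", states)
  if (variant == "degree") {
    md <- rowMeans(degrees)
    score <- ifelse(md > 0, score / md, 0)
  }

  ord <- order(-score, nodes)
  tab <- data.frame(node = nodes, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  tab <- cbind(tab, as.data.frame(degrees))
  rownames(tab) <- NULL
  class(tab) <- c("RewiringTable", "data.frame")
  attr(tab, "mode") <- mode
  attr(tab, "variant") <- variant
  tab
}

adjacency_matrix <- function(network, nodes, mode) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e)) {
    w <- if (mode == "binary") rep(1, nrow(e)) else abs(e$weight)
    A[cbind(e$source, e$target)] <- w
    A[cbind(e$target, e$source)] <- w
  }
  A
}

#' Top rewired nodes above a score cutoff
#'
#' @param table a `RewiringTable`.
#' @param cutoff nonnegative score cutoff; nodes with `score >= cutoff` are
#'   kept (default 5, the cutoff used for published rewiring tables).
#' @return the qualifying rows, sorted by descending score with ties broken
#'   lexicographically by node ID.
#' @export
top_rewired <- function(table, cutoff = 5) {
  stopifnot(inherits(table, "data.frame"))
  if (cutoff < 0) stop("cutoff must be nonnegative")
  keep <- table[table$score >= cutoff, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$node), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Ranked rewiring report for both sign classes
#'
#' @param positive,negative `RewiringTable`s computed on the
#'   positive-correlation and negative-correlation networks.
#' @param cutoff score cutoff applied to both tables (default 5).
#' @return A `RewiringReport`: list with elements `positive` and `negative`
#'   holding the ranked, cutoff-filtered tables.
#' @export
rewiring_report <- function(positive, negative, cutoff = 5) {
  structure(list(positive = top_rewired(positive, cutoff),
                 negative = top_rewired(negative, cutoff),
                 cutoff = cutoff),
            class = "RewiringReport")
}

#' @export
print.RewiringReport <- function(x, ...) {
  for (sgn in c("positive", "negative")) {
    cat(sprintf("Top rewired nodes (%s networks, score >= %s):\n",
                sgn, format(x$cutoff)))
    t <- x[[sgn]]
    if (!nrow(t)) cat("  (none)\n")
    else print(t[, c("node", "score")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a rewiring table as TSV
#'
#' @param table a `RewiringTable`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_rewiring_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Consensus differential network against a reference state
#'
#' Compares condition networks to a reference network of the same sign
#' class and threshold. An edge is *gained* when it is absent from the
#' reference but present in every condition network, and *lost* when it is
#' present in the reference but absent from every condition network. Edges
#' that change in only some conditions appear in neither set, so the result
#' is the consensus of all conditions.
#'
#' @param reference a `SignedNetwork` (the reference state, e.g. NC).
#' @param conditions non-empty list of `SignedNetwork`s (e.g. MCI and AD).
#' @return A `DifferentialNetwork`: list with `reference`, `conditions`
#'   (state labels), `sign`, `threshold`, `nodes`, `gained` and `lost`
#'   (data.frames `source, target`).
#' @export
consensus_differential <- function(reference, conditions) {
  stopifnot(inherits(reference, "SignedNetwork"))
  if (!length(conditions)) stop("need at least one condition network")
  stopifnot(all(vapply(conditions, inherits, logical(1), "SignedNetwork")))
  for (nw in conditions) {
    if (!identical(nw$sign, reference$sign))
      stop("mixed sign classes: reference is ", reference$sign,
           ", condition is ", nw$sign)
    if (!identical(nw$threshold, reference$threshold))
      stop("condition networks must share the reference threshold")
    if (!identical(sort(nw$nodes), sort(reference$nodes)))
      stop("networks must share an identical node set")
  }
  key <- function(nw) paste(nw$edges$source, nw$edges$target, sep = "\t")
  kref <- key(reference)
  kcond <- lapply(conditions, key)
  gained <- sort(setdiff(Reduce(intersect, kcond), kref))
  lost <- sort(setdiff(kref, Reduce(union, kcond)))
  unkey <- function(k) {
    if (!length(k))
      return(data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(k, "\t", fixed = TRUE))
    data.frame(source = parts[, 1], target = parts[, 2],
               stringsAsFactors = FALSE)
  }
  structure(list(
    reference = as.character(reference$state),
    conditions = vapply(conditions, function(nw) as.character(nw$state),
                        character(1)),
    sign = reference$sign, threshold = reference$threshold,
    nodes = reference$nodes, gained = unkey(gained), lost = unkey(lost)),
    class = "DifferentialNetwork")
}

#' @export
print.DifferentialNetwork <- function(x, ...) {
  cat(sprintf(
    "DifferentialNetwork [%s, T = %s] %s vs %s: %d gained, %d lost\n",
    x$sign, format(x$threshold), paste(x$conditions, collapse = "+"),
    x$reference, nrow(x$gained), nrow(x$lost)))
  invisible(x)
}

#' Export a differential network
#'
#' Writes the gained/lost edge sets as a TSV edge table, a GraphML file
#' (edge attribute `change` in `{gained, lost}`), or a SIF file (interaction
#' type `gained`/`lost`).
#'
#' @param diffnet a `DifferentialNetwork`.
#' @param path output file.
#' @param format `"table"`, `"graphml"` or `"sif"`.
#' @return invisibly, `path`.
#' @export
export_differential <- function(diffnet, path,
                                format = c("table", "graphml", "sif")) {
  stopifnot(inherits(diffnet, "DifferentialNetwork"))
  format <- match.arg(format)
  g <- diffnet$gained; l <- diffnet$lost
  edges <- rbind(
    if (nrow(g)) cbind(g, change = "gained") else NULL,
    if (nrow(l)) cbind(l, change = "lost") else NULL)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        change = character(), stringsAsFactors = FALSE)
  if (format == "table") {
    edges$sign <- rep(diffnet$sign, nrow(edges))
    edges$reference <- rep(diffnet$reference, nrow(edges))
    data.table::fwrite(edges, path, sep = "\t", quote = FALSE)
  } else if (format == "graphml") {
    gr <- igraph::graph_from_data_frame(
      edges, directed = FALSE, vertices = data.frame(name = diffnet$nodes))
    gr <- igraph::set_graph_attr(gr, "sign", diffnet$sign)
    gr <- igraph::set_graph_attr(gr, "reference", diffnet$reference)
    igraph::write_graph(gr, path, format = "graphml")
  } else {
    lines <- if (nrow(edges))
      paste(edges$source, edges$change, edges$target, sep = "\t")
    else character(0)
    isolated <- setdiff(diffnet$nodes, unique(c(edges$source, edges$target)))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
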