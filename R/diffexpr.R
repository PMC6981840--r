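#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, as used for the per-probe condition-vs-reference direction
#' calls. When both groups are constant the test statistic is undefined: by
#' convention p = 1 when the constants agree (no evidence of difference)
#' and p = 0 when they differ, both flagged.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `statistic`, `df`, `p.value`, `flagged`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_test needs >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- mean(a) == mean(b)
    return(list(statistic = if (equal) 0 else Inf, df = NA_real_,
                p.value = if (equal) 1 else 0, flagged = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, flagged = FALSE)
}

#' False-discovery-rate adjustment
#'
#' Step-up adjustment of a p-value vector, Benjamini-Hochberg by default or
#' Benjamini-Yekutieli on request; input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"BY"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no NA")
  stats::p.adjust(p, method = method)
}

#' Direction-of-expression table with display rules
#'
#' For each retained probe and each condition state, tests the condition
#' against the reference state with a Welch t-test, adjusts p-values across
#' probes within each contrast (FDR), and derives the published-table
#' display convention: direction alone when adjusted p <= `p_show`;
#' direction plus the p-value when `p_show` < p <= `p_dash`; a dash when
#' p > `p_dash` (direction suppressed entirely).
#'
#' @param dataset a `FilteredDataset` from [run_filter_cascade()], or an
#'   `ExpressionMatrix` (then `labels` must be given).
#' @param labels sample labels; taken from the dataset when omitted.
#' @param reference reference state (default `"NC"`).
#' @param conditions condition states compared against the reference
#'   (default the remaining label levels, i.e. MCI and AD).
#' @param p_show adjusted-p threshold below or at which only the direction
#'   is displayed (default 0.1).
#' @param p_dash adjusted-p threshold above which the display is a dash
#'   (default 0.75).
#' @param method FDR method passed to [bh_adjust()].
#' @return A `DirectionTable` data.frame: `probe`, then per condition
#'   `<cond>_direction`, `<cond>_p_adj`, `<cond>_display`.
#' @export
direction_table <- function(dataset, labels = NULL, reference = "NC",
                            conditions = NULL, p_show = 0.1, p_dash = 0.75,
                            method = "BH") {
  if (inherits(dataset, "FilteredDataset")) {
    x <- dataset$data
    if (is.null(labels)) labels <- dataset$labels
  } else if (inherits(dataset, "ExpressionMatrix")) {
    x <- dataset
  } else stop("dataset must be a FilteredDataset or ExpressionMatrix")
  if (is.null(labels)) stop("labels are required")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(x$values))
    stop("labels must be aligned with the samples")
  if (is.null(conditions)) conditions <- setdiff(levels(labels), reference)
  missing_states <- setdiff(c(reference, conditions), levels(labels))
  if (length(missing_states))
    stop("state(s) absent from the data: ",
         paste(missing_states, collapse = ", "))
  if (p_show >= p_dash) stop("need p_show < p_dash")

  v <- x$values
  ref_idx <- labels == reference
  out <- data.frame(probe = rownames(v), stringsAsFactors = FALSE)
  for (cond in conditions) {
    ci <- labels == cond
    diff <- rowMeans(v[, ci, drop = FALSE]) -
      rowMeans(v[, ref_idx, drop = FALSE])
    praw <- vapply(seq_len(nrow(v)), function(i)
      welch_test(v[i, ci], v[i, ref_idx])$p.value, numeric(1))
    padj <- bh_adjust(praw, method = method)
    dir <- ifelse(diff >= 0, "Up", "Down")
    out[[paste0(cond, "_direction")]] <- dir
    out[[paste0(cond, "_p_adj")]] <- padj
    out[[paste0(cond, "_display")]] <- format_direction(dir, padj,
                                                        p_show, p_dash)
  }
  rownames(out) <- NULL
  class(out) <- c("DirectionTable", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "conditions") <- conditions
  out
}

#' Display string for a direction call
#'
#' Encodes the three p-value bands used in the published gene table:
#' `p <= p_show` shows the direction alone, `p_show < p <= p_dash` appends
#' the p-value, and `p > p_dash` collapses to `"-"` regardless of
#' direction. The bands partition \[0, 1\] exhaustively and exclusively.
#'
#' @param direction `"Up"` or `"Down"` per probe.
#' @param p_adj adjusted p-values.
#' @param p_show,p_dash band boundaries (defaults 0.1 and 0.75).
#' @return character vector of display strings.
#' @export
format_direction <- function(direction, p_adj, p_show = 0.1, p_dash = 0.75) {
  ifelse(p_adj > p_dash, "-",
         ifelse(p_adj > p_show,
                paste0(direction, ", p = ", vapply(p_adj, function(p)
                  format(signif(p, 3)), character(1))),
                direction))
}

#' Write a direction table as TSV
#'
#' @param tab a `DirectionTable`.
#' @param path output file.
#' @param annotations optional named character vector mapping probe IDs to
#'   gene labels for the `gene_label` column (defaults to the probe ID).
#' @return invisibly, `path`.
#' @export
write_direction_table <- function(tab, path, annotations = NULL) {
  out <- as.data.frame(tab)
  gene <- if (is.null(annotations)) out$probe else
    unname(ifelse(is.na(annotations[out$probe]), out$probe,
                  annotations[out$probe]))
  out <- data.frame(probe = out$probe, gene_label = gene,
                    out[, setdiff(names(out), "probe"), drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
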