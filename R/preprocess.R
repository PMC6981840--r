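#' Assign a diagnosis to each expression sample by nearest exam date
#'
#' Each sample receives the label of the subject's diagnosis record whose
#' exam date is on or nearest to the sample collection date. Ties in
#' absolute distance are broken toward the earlier exam record, which keeps
#' the merge deterministic. Samples whose subject has no diagnosis record at
#' all are dropped with a warning (they cannot be placed in a state group).
#'
#' @param sample_meta data.frame with columns `SampleID`, `SubjectID`,
#'   `CollectionDate` (Date or ISO-8601 string).
#' @param diagnoses data.frame with columns `SubjectID`, `ExamDate`,
#'   `Diagnosis` (see [read_diagnosis()]).
#' @return data.frame with one row per retained sample: `SampleID`,
#'   `SubjectID`, `CollectionDate`, `Diagnosis`, `ExamDate`, `days_offset`
#'   (absolute days between exam and collection).
#' @examples
#' meta <- data.frame(SampleID = "s1", SubjectID = "A",
#'                    CollectionDate = as.Date("2010-05-01"))
#' recs <- data.frame(SubjectID = "A",
#'                    ExamDate = as.Date(c("2010-04-01", "2010-07-01")),
#'                    Diagnosis = c("MCI", "AD"))
#' assign_diagnosis(meta, recs)$Diagnosis  # "MCI": 30 days beats 61
#' @export
assign_diagnosis <- function(sample_meta, diagnoses) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0)
    stop("diagnosis table is empty")
  sm <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("SampleID", "SubjectID", "CollectionDate")
  if (!all(need %in% names(sm)))
    stop("sample_meta needs columns ", paste(need, collapse = ", "))
  cd <- parse_dates(sm$CollectionDate, "CollectionDate")
  ed <- parse_dates(diagnoses$ExamDate, "ExamDate")

  out <- vector("list", nrow(sm))
  dropped <- character(0)
  for (i in seq_len(nrow(sm))) {
    idx <- which(diagnoses$SubjectID == sm$SubjectID[i])
    if (!length(idx)) {
      dropped <- c(dropped, sm$SampleID[i])
      next
    }
    dist <- abs(as.integer(ed[idx] - cd[i]))
    cand <- idx[dist == min(dist)]
    pick <- cand[which.min(ed[cand])]          # earlier record wins ties
    out[[i]] <- data.frame(
      SampleID = sm$SampleID[i], SubjectID = sm$SubjectID[i],
      CollectionDate = cd[i], Diagnosis = diagnoses$Diagnosis[pick],
      ExamDate = ed[pick], days_offset = min(dist),
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning(length(dropped), " sample(s) dropped (no diagnosis records): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(SampleID = character(), SubjectID = character(),
                      CollectionDate = as.Date(character()),
                      Diagnosis = character(),
                      ExamDate = as.Date(character()),
                      days_offset = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

parse_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable ", what, " in row(s) ",
         paste(which(is.na(d)), collapse = ", "))
  d
}

#' Probe filter settings
#'
#' Defaults mirror the standard genefilter-style blood-array cascade: keep a
#' probe when its linear-scale coefficient of variation lies in
#' \[`cv_min`, `cv_max`\] = \[0.7, 10\] and at least `min_frac` = 20% of
#' samples exceed intensity `intensity_cut` = 100; then keep survivors with
#' one-way ANOVA p < `anova_alpha` = 0.1 across the diagnostic groups.
#'
#' @param cv_min,cv_max coefficient-of-variation window (0 < cv_min <
#'   cv_max).
#' @param intensity_cut intensity a sample must strictly exceed to count
#'   toward `min_frac`.
#' @param min_frac minimum fraction of samples above `intensity_cut`
#'   (inclusive).
#' @param anova_alpha ANOVA retention level in (0, 1); probes kept when
#'   p < alpha (strict).
#' @param anova_scale scale the ANOVA runs on: `"linear"` (default, same
#'   de-normalized scale as the variation filter) or `"log2"`.
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(cv_min = 0.7, cv_max = 10, intensity_cut = 100,
                          min_frac = 0.2, anova_alpha = 0.1,
                          anova_scale = c("linear", "log2")) {
  anova_scale <- match.arg(anova_scale)
  if (!(cv_min > 0 && cv_min < cv_max))
    stop("need 0 < cv_min < cv_max")
  if (intensity_cut <= 0) stop("intensity_cut must be positive")
  if (!(min_frac > 0 && min_frac <= 1)) stop("min_frac must be in (0, 1]")
  if (!(anova_alpha > 0 && anova_alpha < 1))
    stop("anova_alpha must be in (0, 1)")
  structure(list(cv_min = cv_min, cv_max = cv_max,
                 intensity_cut = intensity_cut, min_frac = min_frac,
                 anova_alpha = anova_alpha, anova_scale = anova_scale),
            class = "FilterConfig")
}

#' Variation / intensity probe filter (stage 1)
#'
#' Operates on linear (de-normalized) intensities, pooled over all samples
#' regardless of group. A probe passes when `cv_min <= sd/mean <= cv_max`
#' (sample standard deviation, n-1 denominator) and the fraction of samples
#' with intensity strictly greater than `intensity_cut` is at least
#' `min_frac`. A probe with mean 0 has an undefined CV; it is excluded and
#' flagged rather than raising an error.
#'
#' @param x an `ExpressionMatrix` on the linear scale with >= 2 samples.
#' @param cfg a [filter_config()].
#' @return list with `keep` (named logical) and `stats` (data.frame `probe,
#'   mean, sd, cv, frac_above_cut, pass, flagged`).
#' @export
filter_variation <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(cfg, "FilterConfig"))
  if (x$scale != "linear")
    stop("variation filter requires linear-scale intensities; call delog() first")
  v <- x$values
  if (ncol(v) < 2) stop("need >= 2 samples to compute a CV")
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  frac <- rowMeans(v > cfg$intensity_cut)
  pass <- !is.na(cv) & cv >= cfg$cv_min & cv <= cfg$cv_max &
    frac >= cfg$min_frac
  stats <- data.frame(probe = rownames(v), mean = mu, sd = s, cv = cv,
                      frac_above_cut = frac, pass = pass,
                      flagged = is.na(cv), stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  list(keep = stats::setNames(pass, rownames(v)), stats = stats)
}

#' One-way ANOVA probe filter (stage 2)
#'
#' Fixed-effects one-way ANOVA of each probe across the diagnostic groups
#' (via `stats::oneway.test(var.equal = TRUE)`); probes are kept when
#' p < `alpha`. Degenerate probes whose ANOVA is undefined (zero variance
#' everywhere, hence identical group means) are assigned p = 1 and flagged;
#' the pathological converse (zero within-group variance but differing
#' means) is assigned p = 0 and flagged.
#'
#' @param x an `ExpressionMatrix` (any scale; the cascade decides which
#'   scale to feed in).
#' @param labels group label per sample (character or factor), aligned with
#'   `sample_ids(x)`.
#' @param alpha retention level; keep iff p < alpha.
#' @return list with `keep` (named logical) and `stats` (data.frame `probe,
#'   anova_p, pass, flagged`).
#' @export
filter_anova <- function(x, labels, alpha = 0.1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(x$values))
    stop("labels must be aligned with the samples (got ", length(labels),
         " labels for ", ncol(x$values), " samples)")
  if (nlevels(labels) < 2) stop("need >= 2 groups for ANOVA")
  if (any(table(labels) < 2)) stop("every group needs >= 2 samples")
  v <- x$values
  p <- numeric(nrow(v)); flagged <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    y <- v[i, ]
    gm <- tapply(y, labels, mean)
    wv <- tapply(y, labels, stats::var)
    if (all(wv == 0)) {                       # no within-group variation
      flagged[i] <- TRUE
      p[i] <- if (max(gm) == min(gm)) 1 else 0
    } else {
      p[i] <- stats::oneway.test(y ~ labels, var.equal = TRUE)$p.value
      if (is.na(p[i])) { p[i] <- 1; flagged[i] <- TRUE }
    }
  }
  pass <- p < alpha
  stats <- data.frame(probe = rownames(v), anova_p = p, pass = pass,
                      flagged = flagged, stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  list(keep = stats::setNames(pass, rownames(v)), stats = stats)
}

#' Two-stage probe filter cascade
#'
#' De-normalizes a log2 matrix, applies the variation/intensity filter, then
#' the ANOVA filter on the stage-1 survivors. Probe order is preserved from
#' the input. Zero survivors at either stage produce a valid empty result
#' with a warning, not an error.
#'
#' @param x an `ExpressionMatrix` on the log2 scale (RMA output).
#' @param labels diagnosis label per sample, aligned with `sample_ids(x)`.
#' @param cfg a [filter_config()].
#' @return A `FilteredDataset`: list with `data` (linear-scale
#'   `ExpressionMatrix` of survivors), `labels` (factor), `report`
#'   (`FilterReport` data.frame: `probe, cv, frac_above_cut, pass_stage1,
#'   anova_p, pass_stage2`, with per-stage survivor counts in attribute
#'   `counts`), and `config`.
#' @export
run_filter_cascade <- function(x, labels, cfg = filter_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("the cascade expects RMA-style log2 input; got linear scale")
  labels <- droplevels(as.factor(labels))
  lin <- delog(x)

  s1 <- filter_variation(lin, cfg)
  report <- data.frame(probe = s1$stats$probe, cv = s1$stats$cv,
                       frac_above_cut = s1$stats$frac_above_cut,
                       pass_stage1 = s1$stats$pass,
                       anova_p = NA_real_, pass_stage2 = FALSE,
                       stringsAsFactors = FALSE)
  surv1 <- names(s1$keep)[s1$keep]

  if (length(surv1) == 0) {
    warning("no probes survived the variation/intensity filter")
    surv2 <- character(0)
  } else {
    stage2_in <- subset_probes(if (cfg$anova_scale == "linear") lin else x,
                               surv1)
    s2 <- filter_anova(stage2_in, labels, cfg$anova_alpha)
    report$anova_p[match(surv1, report$probe)] <- s2$stats$anova_p
    report$pass_stage2[match(surv1, report$probe)] <- s2$stats$pass
    surv2 <- names(s2$keep)[s2$keep]
    if (length(surv2) == 0)
      warning("no probes survived the ANOVA filter")
  }

  attr(report, "counts") <- c(n_in = nrow(x$values),
                              n_stage1 = length(surv1),
                              n_stage2 = length(surv2))
  class(report) <- c("FilterReport", "data.frame")
  data <- if (length(surv2)) subset_probes(lin, surv2) else
    expression_matrix(lin$values[character(0), , drop = FALSE], "linear")
  structure(list(data = data, labels = labels, report = report,
                 config = cfg), class = "FilteredDataset")
}

#' @export
print.FilteredDataset <- function(x, ...) {
  n <- attr(x$report, "counts")
  cat(sprintf("FilteredDataset: %d -> %d (variation/intensity) -> %d (ANOVA) probes; %d samples\n",
              n["n_in"], n["n_stage1"], n["n_stage2"], ncol(x$data$values)))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report the `report` element of a [run_filter_cascade()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t", quote = FALSE)
  invisible(path)
}
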