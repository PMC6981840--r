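#' Probes-by-samples expression matrix with an explicit intensity scale
#'
#' Thin container for a numeric matrix of expression values (rows = probe
#' sets, columns = samples) that records whether the values are RMA-style
#' log2 intensities or de-normalized linear intensities. The scale flag is
#' what lets downstream filters refuse to run on the wrong scale, and lets
#' [delog()] refuse to exponentiate twice.
#'
#' @param values numeric matrix with unique probe IDs as rownames and sample
#'   IDs as colnames. All values must be finite.
#' @param scale `"log2"` (RMA output) or `"linear"` (de-normalized
#'   intensities).
#' @return An `ExpressionMatrix` object (list with elements `values` and
#'   `scale`).
#' @examples
#' m <- matrix(rnorm(6, 7), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2", "S3")))
#' x <- expression_matrix(m, "log2")
#' delog(x)$scale
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("probe IDs are required as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("sample IDs are required as colnames")
  if (is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Reverse RMA log2 scaling
#'
#' Converts a log2-scale matrix to linear intensities (`2^x`, the inverse of
#' the RMA log step), preserving shape and IDs. Calling it on a matrix that
#' is already linear is an error, which prevents accidental double
#' exponentiation.
#'
#' @param x an `ExpressionMatrix` on the log2 scale.
#' @return An `ExpressionMatrix` on the linear scale.
#' @seealso [relog()] for the inverse.
#' @export
delog <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("matrix is already on the linear scale; refusing to exponentiate twice")
  expression_matrix(2^x$values, "linear")
}

#' Return to the log2 scale
#'
#' @param x an `ExpressionMatrix` on the linear scale with strictly positive
#'   values.
#' @return An `ExpressionMatrix` on the log2 scale.
#' @export
relog <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("matrix is already on the log2 scale")
  if (any(x$values <= 0))
    stop("linear intensities must be positive to take log2")
  expression_matrix(log2(x$values), "log2")
}

## subset rows (probes), keeping the scale flag
subset_probes <- function(x, probes) {
  expression_matrix(x$values[probes, , drop = FALSE], x$scale)
}

#' Read an expression matrix from CSV
#'
#' Expects the layout written by [write_fixture()]: a `ProbeSetID` first
#' column and one column per sample, cells holding intensities on the scale
#' given by `scale` (log2 by default, matching RMA-normalized exports).
#'
#' @param path path to the CSV file.
#' @param scale scale of the stored values, `"log2"` or `"linear"`.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale = "log2") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2)
    stop("expression CSV needs a probe-ID column plus sample columns: ", path)
  probes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  expression_matrix(m, scale)
}

#' Read a diagnosis table from CSV
#'
#' Columns `SubjectID,ExamDate,Diagnosis`; ISO-8601 dates; labels restricted
#' to the given states. A subject may have several dated records (the
#' nearest-date rule in [assign_diagnosis()] picks one per sample).
#'
#' @param path path to the CSV file.
#' @param states allowed diagnosis labels.
#' @return data.frame with columns `SubjectID` (character), `ExamDate`
#'   (Date), `Diagnosis` (character).
#' @export
read_diagnosis <- function(path, states = c("NC", "MCI", "AD")) {
  if (!file.exists(path)) stop("diagnosis file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character")
  need <- c("SubjectID", "ExamDate", "Diagnosis")
  if (!all(need %in% names(dt)))
    stop("diagnosis CSV must have columns ", paste(need, collapse = ", "))
  dates <- as.Date(dt$ExamDate, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable ExamDate in diagnosis row(s) ",
         paste(which(is.na(dates)), collapse = ", "), " of ", path)
  bad <- setdiff(unique(dt$Diagnosis), states)
  if (length(bad))
    stop("diagnosis labels outside {", paste(states, collapse = ", "),
         "}: ", paste(bad, collapse = ", "))
  data.frame(SubjectID = dt$SubjectID, ExamDate = dates,
             Diagnosis = dt$Diagnosis, stringsAsFactors = FALSE)
}

#' Read per-sample metadata (subject and collection date) from CSV
#'
#' @param path CSV with columns `SampleID,SubjectID,CollectionDate`.
#' @return data.frame with a Date-class `CollectionDate`.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("sample metadata file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character")
  need <- c("SampleID", "SubjectID", "CollectionDate")
  if (!all(need %in% names(dt)))
    stop("sample metadata CSV must have columns ", paste(need, collapse = ", "))
  dates <- as.Date(dt$CollectionDate, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable CollectionDate in row(s) ",
         paste(which(is.na(dates)), collapse = ", "), " of ", path)
  data.frame(SampleID = dt$SampleID, SubjectID = dt$SubjectID,
             CollectionDate = dates, stringsAsFactors = FALSE)
}
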