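#' End-to-end pipeline configuration
#'
#' Collects every tunable of the expression-to-networks flow. Defaults
#' reproduce the standard analysis: filter cascade at CV 0.7-10 /
#' intensity > 100 in >= 20% / ANOVA p < 0.1; networks at thresholds 0.1
#' and 0.3; network comparisons (rewiring and consensus differential) on
#' the threshold-0.1 binary edge tables with NC as reference; rewiring
#' report cutoff 5.
#'
#' @param filter a [filter_config()].
#' @param thresholds thresholds at which edge tables are built.
#' @param comparison_threshold threshold whose networks feed the rewiring
#'   and consensus comparisons (must be among `thresholds`).
#' @param basic_threshold threshold of the "basic" co-expression networks
#'   exported as GraphML/SIF (must be among `thresholds`).
#' @param score_mode `"binary"` or `"weighted"` adjacency for rewiring.
#' @param score_variant `"raw"`, `"degree"` or `"unsquared"` (see
#'   [rewiring_scores()]).
#' @param reference reference state for the consensus comparison.
#' @param rewiring_cutoff score cutoff of the rewiring report.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(filter = filter_config(),
                            thresholds = c(0.1, 0.3),
                            comparison_threshold = 0.1,
                            basic_threshold = 0.3,
                            score_mode = "binary",
                            score_variant = "raw",
                            reference = "NC",
                            rewiring_cutoff = 5) {
  if (any(thresholds < 0)) stop("thresholds must be nonnegative")
  if (!comparison_threshold %in% thresholds)
    stop("comparison_threshold must be one of the thresholds")
  if (!basic_threshold %in% thresholds)
    stop("basic_threshold must be one of the thresholds")
  structure(list(filter = filter, thresholds = thresholds,
                 comparison_threshold = comparison_threshold,
                 basic_threshold = basic_threshold,
                 score_mode = score_mode, score_variant = score_variant,
                 reference = reference,
                 rewiring_cutoff = rewiring_cutoff),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; filter
#' settings live under a `filter` key with [filter_config()] argument
#' names. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  fargs <- y$filter %||% list()
  y$filter <- NULL
  args <- y
  args$filter <- do.call(filter_config, fargs)
  if (!is.null(args$thresholds)) args$thresholds <- unlist(args$thresholds)
  do.call(pipeline_config, args)
}

#' Run the full expression-to-networks pipeline
#'
#' Orchestrates the whole flow on files or in-memory objects: diagnosis
#' merge, de-normalization and probe filtering, direction table, per-state
#' signed networks at every threshold, rewiring scores (both sign classes)
#' and consensus differential networks against the reference state. All
#' artifacts are written under `out_dir` together with a JSON manifest
#' recording the resolved parameters, per-stage counts and per-stage wall
#' times. The run is deterministic given fixed inputs and configuration.
#'
#' Artifacts: `filter_report.tsv`, `direction_table.tsv`,
#' `edges_<state>_<sign>_T<threshold>.tsv` for every state x sign x
#' threshold, `rewiring_<sign>.tsv` and the cutoff-filtered
#' `rewiring_report_<sign>.tsv`, `diffnet_<sign>.tsv/.graphml/.sif`, basic
#' networks `basic_<state>_<sign>.graphml`, and `manifest.json`.
#'
#' @param expression path to an expression CSV (log2 scale) or an
#'   `ExpressionMatrix`.
#' @param diagnosis path to a diagnosis CSV or a data.frame
#'   (`SubjectID,ExamDate,Diagnosis`).
#' @param out_dir output directory (created if missing).
#' @param sample_meta path/data.frame of per-sample subject and collection
#'   date; may be `NULL` when every subject has exactly one diagnosis
#'   record, in which case samples are matched to subjects by ID.
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(expression, diagnosis, out_dir,
                         sample_meta = NULL, config = pipeline_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  say <- function(...) if (!quiet) message(...)
  timings <- c()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- round(dt, 3)
    say(sprintf("[%s] done in %.2fs", name, dt))
    res
  }

  x <- stage("load", function() {
    if (inherits(expression, "ExpressionMatrix")) expression
    else read_expression(expression, scale = "log2")
  })
  diag <- if (is.data.frame(diagnosis)) diagnosis else read_diagnosis(diagnosis)
  meta <- if (is.null(sample_meta)) NULL
          else if (is.data.frame(sample_meta)) sample_meta
          else read_sample_meta(sample_meta)

  assigned <- stage("diagnosis_merge", function() {
    if (is.null(meta)) {
      if (anyDuplicated(diag$SubjectID))
        stop("subjects have multiple diagnosis records; ",
             "sample_meta with collection dates is required")
      meta <<- data.frame(SampleID = sample_ids(x),
                          SubjectID = sample_ids(x),
                          CollectionDate = diag$ExamDate[
                            match(sample_ids(x), diag$SubjectID)],
                          stringsAsFactors = FALSE)
    }
    a <- assign_diagnosis(meta, diag)
    a <- a[a$SampleID %in% sample_ids(x), , drop = FALSE]
    a
  })
  n_input_samples <- ncol(x$values)
  keep <- match(assigned$SampleID, sample_ids(x))
  x <- expression_matrix(x$values[, keep, drop = FALSE], x$scale)
  labels <- factor(assigned$Diagnosis)

  filtered <- stage("filter_cascade", function()
    run_filter_cascade(x, labels, config$filter))
  files <- c(filter_report = file.path(out_dir, "filter_report.tsv"))
  write_filter_report(filtered$report, files["filter_report"])
  counts <- as.list(attr(filtered$report, "counts"))

  n_surv <- nrow(filtered$data$values)
  edge_counts <- list()
  manifest_nets <- NULL

  dir_tab <- stage("direction_table", function() {
    if (n_surv == 0) return(NULL)
    direction_table(filtered, reference = config$reference)
  })
  files["direction_table"] <- file.path(out_dir, "direction_table.tsv")
  if (is.null(dir_tab)) {
    writeLines("probe", files["direction_table"])
  } else write_direction_table(dir_tab, files["direction_table"])

  if (n_surv >= 2) {
    nets <- stage("networks", function()
      build_state_networks(filtered, thresholds = config$thresholds))
    for (tl in names(nets$networks)) for (sgn in names(nets$networks[[tl]]))
      for (st in names(nets$networks[[tl]][[sgn]])) {
        nw <- nets$networks[[tl]][[sgn]][[st]]
        f <- file.path(out_dir, sprintf("edges_%s_%s_T%s.tsv", st, sgn, tl))
        export_edge_table(nw, f)
        files[sprintf("edges_%s_%s_T%s", st, sgn, tl)] <- f
        edge_counts[[sprintf("%s_%s_T%s", st, sgn, tl)]] <- nrow(nw$edges)
      }

    bl <- format(config$basic_threshold)
    for (sgn in c("positive", "negative")) for (st in nets$states) {
      f <- file.path(out_dir, sprintf("basic_%s_%s.graphml", st, sgn))
      export_graphml(nets$networks[[bl]][[sgn]][[st]], f)
      files[sprintf("basic_%s_%s", st, sgn)] <- f
    }

    cl <- format(config$comparison_threshold)
    rew <- stage("rewiring", function() {
      lapply(c(positive = "positive", negative = "negative"), function(sgn)
        rewiring_scores(nets$networks[[cl]][[sgn]],
                        mode = config$score_mode,
                        variant = config$score_variant))
    })
    for (sgn in names(rew)) {
      f <- file.path(out_dir, sprintf("rewiring_%s.tsv", sgn))
      write_rewiring_table(rew[[sgn]], f)
      files[sprintf("rewiring_%s", sgn)] <- f
    }
    report <- rewiring_report(rew$positive, rew$negative,
                              cutoff = config$rewiring_cutoff)
    for (sgn in c("positive", "negative")) {
      f <- file.path(out_dir, sprintf("rewiring_report_%s.tsv", sgn))
      data.table::fwrite(as.data.frame(report[[sgn]]), f, sep = "\t",
                         quote = FALSE)
      files[sprintf("rewiring_report_%s", sgn)] <- f
    }

    diffs <- stage("consensus_differential", function() {
      if (!config$reference %in% nets$states)
        stop("reference state ", config$reference, " not present")
      conds <- setdiff(nets$states, config$reference)
      lapply(c(positive = "positive", negative = "negative"), function(sgn) {
        nws <- nets$networks[[cl]][[sgn]]
        consensus_differential(nws[[config$reference]], nws[conds])
      })
    })
    for (sgn in names(diffs)) {
      for (fmt in c("table", "graphml", "sif")) {
        ext <- c(table = "tsv", graphml = "graphml", sif = "sif")[[fmt]]
        f <- file.path(out_dir, sprintf("diffnet_%s.%s", sgn, ext))
        export_differential(diffs[[sgn]], f, format = fmt)
        files[sprintf("diffnet_%s_%s", sgn, fmt)] <- f
      }
    }
    manifest_nets <- list(
      states = nets$states, thresholds = config$thresholds,
      edge_counts = edge_counts,
      rewiring_top = lapply(report[c("positive", "negative")],
                            function(t) t$node),
      differential = lapply(diffs, function(d)
        list(gained = nrow(d$gained), lost = nrow(d$lost))))
  } else {
    warning("fewer than 2 probes survived filtering; network stages skipped")
  }

  manifest <- list(
    package = "coexdiff",
    version = as.character(utils::packageVersion("coexdiff")),
    parameters = list(
      filter = unclass(config$filter), thresholds = config$thresholds,
      comparison_threshold = config$comparison_threshold,
      basic_threshold = config$basic_threshold,
      score_mode = config$score_mode, score_variant = config$score_variant,
      reference = config$reference,
      rewiring_cutoff = config$rewiring_cutoff),
    counts = c(counts, list(n_samples = ncol(x$values),
                            n_samples_dropped =
                              n_input_samples - nrow(assigned))),
    networks = manifest_nets,
    files = lapply(as.list(files), basename),
    timings = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("manifest written: ", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Summarize a pipeline run from its manifest
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @return invisibly, the manifest list.
#' @export
summarize_run <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", out_dir)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cat(sprintf("coexdiff %s run in %s\n", m$version, out_dir))
  cat(sprintf("  probes: %d -> %d (variation/intensity) -> %d (ANOVA)\n",
              m$counts$n_in, m$counts$n_stage1, m$counts$n_stage2))
  cat(sprintf("  samples: %d\n", m$counts$n_samples))
  if (!is.null(m$networks)) {
    cat("  edge counts:\n")
    for (k in names(m$networks$edge_counts))
      cat(sprintf("    %-24s %d\n", k, m$networks$edge_counts[[k]]))
    for (sgn in names(m$networks$differential))
      cat(sprintf("  differential (%s): %d gained, %d lost\n", sgn,
                  m$networks$differential[[sgn]]$gained,
                  m$networks$differential[[sgn]]$lost))
  }
  invisible(m)
}
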