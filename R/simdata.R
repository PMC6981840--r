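#' Configuration for the synthetic expression generator
#'
#' Describes a probes-by-samples study with three diagnostic states and
#' plantable structure: per-state mean shifts (differential expression) and
#' per-state correlation blocks. Blocks are generated from a single-factor
#' model in log2 space, `x = lambda * f + sqrt(1 - lambda^2) * eps` with
#' `lambda = sqrt(|r|)`, so the pairwise correlation of two block members
#' is exactly the requested target (negated between members with opposite
#' loading signs). That construction makes the planted ground truth
#' analytically known.
#'
#' @param n_probes number of probes (>= 1). Probe IDs are `P0001, ...`.
#' @param n_per_state samples per diagnostic state (>= 3; Pearson r is
#'   undefined below that).
#' @param states ordered state labels; the first is the reference state.
#' @param de_probes `NULL` or a data.frame with columns `probe`, `state`,
#'   `shift` (log2 mean shift added in that state).
#' @param blocks list of correlation blocks; each block is a list with
#'   `probes` (character vector of probe IDs) and `targets`, a named list
#'   mapping a state to either a single correlation target in \[-1, 1\] or a
#'   list `list(r = target, neg = <probe subset>)` where `neg` names the
#'   members given a negative factor loading. Pairs with opposite loading
#'   signs get correlation `-|r|`; pairs with matching signs get `+|r|`.
#'   States not named in `targets` have no planted correlation for that
#'   block. Blocks active in the same state must not share probes.
#' @param baseline_log2_mean,baseline_log2_sd mean and spread of the
#'   per-probe baseline log2 intensity (probe-to-probe heterogeneity, drawn
#'   once and shared across states). Defaults 7.5 and 0.5, typical of RMA
#'   summaries of blood arrays.
#' @param noise_sd per-sample log2 standard deviation around the probe
#'   baseline. The default 1 puts the linear-scale coefficient of variation
#'   near 0.85, inside the 0.7-10 filter window.
#' @param exam_offset_days exam date of each subject's true diagnosis record
#'   relative to the sample collection date (default 0 = same day).
#' @param decoy_offsets integer vector of day offsets; for each offset every
#'   subject gets an extra diagnosis record with a *different* (cyclically
#'   next) state label, to exercise the nearest-date assignment.
#' @param seed integer RNG seed; identical configs give bit-identical data.
#' @return A validated `SimConfig` object.
#' @seealso [simulate_expression()], [corr_block()]
#' @export
sim_config <- function(n_probes, n_per_state,
                       states = c("NC", "MCI", "AD"),
                       de_probes = NULL, blocks = list(),
                       baseline_log2_mean = 7.5, baseline_log2_sd = 0.5,
                       noise_sd = 1, exam_offset_days = 0L,
                       decoy_offsets = integer(0), seed = 1L) {
  if (!is.numeric(n_probes) || n_probes < 1)
    stop("n_probes must be a positive count")
  if (!is.numeric(n_per_state) || n_per_state < 3)
    stop("n_per_state must be >= 3 (correlation undefined below that)")
  if (length(states) < 2 || anyDuplicated(states))
    stop("states must be >= 2 distinct labels")
  if (baseline_log2_sd <= 0 || noise_sd <= 0)
    stop("baseline_log2_sd and noise_sd must be positive")
  probes <- sprintf("P%04d", seq_len(n_probes))

  if (!is.null(de_probes)) {
    de_probes <- as.data.frame(de_probes, stringsAsFactors = FALSE)
    if (!all(c("probe", "state", "shift") %in% names(de_probes)))
      stop("de_probes needs columns probe, state, shift")
    if (!all(de_probes$probe %in% probes))
      stop("de_probes refers to probes outside the simulated universe")
    if (!all(de_probes$state %in% states))
      stop("de_probes refers to unknown states")
  } else {
    de_probes <- data.frame(probe = character(), state = character(),
                            shift = numeric(), stringsAsFactors = FALSE)
  }

  blocks <- lapply(blocks, normalize_block, probes = probes, states = states)
  for (s in states) {
    used <- unlist(lapply(blocks, function(b)
      if (s %in% names(b$targets)) b$probes else character(0)))
    if (anyDuplicated(used))
      stop("blocks active in state ", s, " share probes; they must be disjoint")
  }

  structure(list(
    n_probes = as.integer(n_probes), n_per_state = as.integer(n_per_state),
    states = as.character(states), probes = probes, de_probes = de_probes,
    blocks = blocks, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
    exam_offset_days = as.integer(exam_offset_days),
    decoy_offsets = as.integer(decoy_offsets), seed = as.integer(seed)),
    class = "SimConfig")
}

#' Declare a planted correlation block
#'
#' Convenience constructor for the `blocks` entries of [sim_config()].
#'
#' @param probes character vector of probe IDs in the block.
#' @param ... named per-state targets, e.g. `MCI = 0.9` or
#'   `AD = list(r = 0.8, neg = c("P0016"))`.
#' @return A block specification list.
#' @examples
#' corr_block(c("P0001", "P0002", "P0003"), MCI = 0.9)
#' @export
corr_block <- function(probes, ...) {
  list(probes = as.character(probes), targets = list(...))
}

normalize_block <- function(block, probes, states) {
  if (!all(c("probes", "targets") %in% names(block)))
    stop("each block needs elements 'probes' and 'targets'")
  bp <- as.character(block$probes)
  if (length(bp) < 2) stop("a correlation block needs >= 2 probes")
  if (!all(bp %in% probes))
    stop("block probes outside the simulated universe: ",
         paste(setdiff(bp, probes), collapse = ", "))
  tg <- block$targets
  if (is.null(names(tg)) || !all(names(tg) %in% states))
    stop("block targets must be named by state")
  tg <- lapply(tg, function(t) {
    if (is.list(t)) {
      r <- t$r; neg <- as.character(t$neg %||% character(0))
    } else {
      r <- t; neg <- character(0)
    }
    if (!is.numeric(r) || length(r) != 1 || abs(r) > 1)
      stop("block correlation target must be a single value in [-1, 1]")
    if (!all(neg %in% bp))
      stop("neg-loading probes must belong to the block")
    if (r < 0 && length(neg) == 0) {
      ## a uniformly negative target is realised by flipping one loading
      ## (exact for 2-probe blocks; larger blocks need an explicit split)
      if (length(bp) > 2)
        stop("negative target on a block of >2 probes needs an explicit ",
             "'neg' probe subset (uniform pairwise negative correlation is ",
             "not representable by a single factor)")
      neg <- bp[2]
      r <- abs(r)
    }
    list(r = r, neg = neg)
  })
  list(probes = bp, targets = tg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## signed loading vector of a block in one state (sqrt(|r|), negated on neg)
block_loadings <- function(block, state) {
  t <- block$targets[[state]]
  if (is.null(t)) return(NULL)
  lam <- sqrt(abs(t$r))
  load <- rep(lam, length(block$probes))
  load[block$probes %in% t$neg] <- -lam
  names(load) <- block$probes
  load
}

## planted signed correlations of a block in one state: data.frame of pairs
block_pairs <- function(block, state) {
  load <- block_loadings(block, state)
  if (is.null(load) || block$targets[[state]]$r == 0)
    return(empty_edges(r = TRUE))
  p <- names(load)
  idx <- utils::combn(length(p), 2)
  a <- p[idx[1, ]]; b <- p[idx[2, ]]
  r <- abs(block$targets[[state]]$r) * sign(load[idx[1, ]] * load[idx[2, ]])
  ord <- a > b
  data.frame(source = ifelse(ord, b, a), target = ifelse(ord, a, b),
             r = as.numeric(r), stringsAsFactors = FALSE)
}

empty_edges <- function(r = FALSE) {
  d <- data.frame(source = character(), target = character(),
                  stringsAsFactors = FALSE)
  if (r) d$r <- numeric()
  d
}

#' Simulate a labelled expression study with known structure
#'
#' Draws a log2-scale probes-by-samples matrix under the factor-model
#' construction of [sim_config()], together with a dated diagnosis table and
#' a [ground truth][GroundTruth] enumerating exactly the planted structure:
#' differentially expressed probes, per-state signed true edges, the
#' consensus gained/lost edges relative to the reference (first) state, and
#' the most-rewired node(s) implied by the planted adjacency.
#'
#' One subject per sample; each subject gets one diagnosis record at
#' `exam_offset_days` from the collection date, labelled with the generating
#' state, plus one decoy record per `decoy_offsets` entry carrying the
#' cyclically next state label.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `expression` (`ExpressionMatrix`, log2 scale),
#'   `diagnoses` (data.frame `SubjectID,ExamDate,Diagnosis`), `sample_meta`
#'   (data.frame `SampleID,SubjectID,CollectionDate`), and `truth`
#'   (`GroundTruth`).
#' @examples
#' cfg <- sim_config(10, 20, blocks = list(corr_block(c("P0001","P0002","P0003"),
#'                                                    MCI = 0.9)), seed = 7)
#' sim <- simulate_expression(cfg)
#' sim$truth$edges_by_state$MCI
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  P <- config$n_probes; n <- config$n_per_state
  states <- config$states; probes <- config$probes

  mu <- rnorm(P, config$baseline_log2_mean, config$baseline_log2_sd)
  names(mu) <- probes

  cols <- list()
  for (s in states) {
    Z <- matrix(rnorm(P * n), P, n, dimnames = list(probes, NULL))
    dev <- Z
    for (b in config$blocks) {
      load <- block_loadings(b, s)
      if (is.null(load)) next
      f <- rnorm(n)
      lam2 <- load^2
      dev[b$probes, ] <- load %o% f + sqrt(1 - lam2) * Z[b$probes, , drop = FALSE]
    }
    mu_s <- mu
    de_s <- config$de_probes[config$de_probes$state == s, , drop = FALSE]
    if (nrow(de_s)) {
      sh <- tapply(de_s$shift, de_s$probe, sum)
      mu_s[names(sh)] <- mu_s[names(sh)] + as.numeric(sh)
    }
    cols[[s]] <- mu_s + config$noise_sd * dev
  }
  values <- do.call(cbind, cols)

  N <- n * length(states)
  subjects <- sprintf("SUBJ%04d", seq_len(N))
  colnames(values) <- subjects
  collection <- as.Date("2010-01-01") + seq_len(N) - 1L
  state_of <- rep(states, each = n)

  diag_list <- list(data.frame(
    SubjectID = subjects, ExamDate = collection + config$exam_offset_days,
    Diagnosis = state_of, stringsAsFactors = FALSE))
  for (off in config$decoy_offsets) {
    decoy_state <- states[(match(state_of, states) %% length(states)) + 1L]
    diag_list[[length(diag_list) + 1L]] <- data.frame(
      SubjectID = subjects, ExamDate = collection + off,
      Diagnosis = decoy_state, stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, diag_list)
  diagnoses <- diagnoses[order(diagnoses$SubjectID, diagnoses$ExamDate), ]
  rownames(diagnoses) <- NULL

  sample_meta <- data.frame(SampleID = subjects, SubjectID = subjects,
                            CollectionDate = collection,
                            stringsAsFactors = FALSE)

  truth <- derive_ground_truth(config)

  list(expression = expression_matrix(values, "log2"),
       diagnoses = diagnoses, sample_meta = sample_meta, truth = truth)
}

#' Planted ground truth of a simulation config
#'
#' @param config a [sim_config()] object.
#' @return A `GroundTruth` object: list with `de_probes` (probe, state,
#'   shift, direction), `edges_by_state` (per state, data.frame
#'   `source,target,r` of planted signed correlations), `consensus_gained` /
#'   `consensus_lost` (data.frame `source,target,sign` relative to the
#'   reference state, per sign class), and `rewired_nodes` (nodes attaining
#'   the maximal planted rewiring score in either sign class).
#' @export
derive_ground_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  states <- config$states
  de <- config$de_probes
  de$direction <- ifelse(de$shift >= 0, "Up", "Down")

  edges_by_state <- lapply(states, function(s) {
    pl <- lapply(config$blocks, block_pairs, state = s)
    e <- do.call(rbind, c(pl, list(empty_edges(r = TRUE))))
    e <- e[order(e$source, e$target), , drop = FALSE]
    rownames(e) <- NULL
    e
  })
  names(edges_by_state) <- states

  keyify <- function(e) paste(e$source, e$target, sep = "\t")
  gained <- lost <- list()
  ref <- states[1]; conds <- states[-1]
  for (sgn in c("positive", "negative")) {
    pick <- function(s) {
      e <- edges_by_state[[s]]
      if (sgn == "positive") e[e$r > 0, , drop = FALSE]
      else e[e$r < 0, , drop = FALSE]
    }
    kref <- keyify(pick(ref))
    kcond <- lapply(conds, function(s) keyify(pick(s)))
    g <- setdiff(Reduce(intersect, kcond), kref)
    l <- setdiff(kref, Reduce(union, kcond))
    tod <- function(k) {
      if (!length(k)) return(cbind(empty_edges(), sign = character()))
      parts <- do.call(rbind, strsplit(k, "\t", fixed = TRUE))
      data.frame(source = parts[, 1], target = parts[, 2], sign = sgn,
                 stringsAsFactors = FALSE)
    }
    gained[[sgn]] <- tod(sort(g)); lost[[sgn]] <- tod(sort(l))
  }
  consensus_gained <- do.call(rbind, gained); rownames(consensus_gained) <- NULL
  consensus_lost <- do.call(rbind, lost); rownames(consensus_lost) <- NULL

  rewired <- character(0)
  for (sgn in c("positive", "negative")) {
    adj <- lapply(states, function(s) {
      e <- edges_by_state[[s]]
      e <- if (sgn == "positive") e[e$r > 0, ] else e[e$r < 0, ]
      A <- matrix(0, config$n_probes, config$n_probes,
                  dimnames = list(config$probes, config$probes))
      if (nrow(e)) {
        A[cbind(e$source, e$target)] <- 1
        A[cbind(e$target, e$source)] <- 1
      }
      A
    })
    C <- Reduce(`+`, adj) / length(adj)
    sc <- Reduce(`+`, lapply(adj, function(A) rowSums((A - C)^2)))
    if (max(sc) > 0)
      rewired <- union(rewired, names(sc)[sc == max(sc)])
  }

  structure(list(de_probes = de, edges_by_state = edges_by_state,
                 consensus_gained = consensus_gained,
                 consensus_lost = consensus_lost,
                 rewired_nodes = sort(rewired)),
            class = "GroundTruth")
}

#' Simulate an unstructured (null) study
#'
#' All probes i.i.d. normal across samples and states on the log2 scale: no
#' mean shifts, no correlation blocks. Used for calibration checks (ANOVA
#' retention at its nominal level, FDR control of the direction table).
#'
#' @param n_probes,n_per_state,seed as in [sim_config()].
#' @param ... further arguments passed to [sim_config()].
#' @return list with `expression`, `diagnoses`, `sample_meta` (no ground
#'   truth; there is nothing planted).
#' @export
simulate_null <- function(n_probes, n_per_state, seed = 1L, ...) {
  sim <- simulate_expression(sim_config(n_probes, n_per_state, seed = seed, ...))
  sim$truth <- NULL
  sim
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Writes `expression.csv` (ProbeSetID + one column per sample),
#' `diagnosis.csv` (SubjectID,ExamDate,Diagnosis), `sample_meta.csv`
#' (SampleID,SubjectID,CollectionDate) and, when a ground truth is given,
#' `truth.json`. With the default `digits = NA` numeric values are written
#' with 17 significant digits, so a read-back round-trip reproduces the
#' in-memory matrix exactly.
#'
#' @param dir output directory (created if missing).
#' @param expression an `ExpressionMatrix`.
#' @param diagnoses diagnosis data.frame as produced by
#'   [simulate_expression()].
#' @param sample_meta per-sample metadata data.frame, or `NULL` to skip.
#' @param truth a `GroundTruth`, or `NULL` to skip.
#' @param digits significant digits for expression values (`NA` = exact
#'   round-trip precision).
#' @return invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(dir, expression, diagnoses, sample_meta = NULL,
                          truth = NULL, digits = NA) {
  stopifnot(inherits(expression, "ExpressionMatrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  files <- c(expression = file.path(dir, "expression.csv"),
             diagnoses = file.path(dir, "diagnosis.csv"))

  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  v <- expression$values
  chr <- matrix(sprintf(fmt, v), nrow(v), dimnames = dimnames(v))
  dt <- data.table::data.table(ProbeSetID = rownames(v))
  dt <- cbind(dt, data.table::as.data.table(chr))
  tryCatch(data.table::fwrite(dt, files["expression"], quote = FALSE),
           error = function(e) stop("writing ", files["expression"], ": ",
                                    conditionMessage(e)))

  dg <- diagnoses
  dg$ExamDate <- format(as.Date(dg$ExamDate), "%Y-%m-%d")
  data.table::fwrite(dg, files["diagnoses"], quote = FALSE)

  if (!is.null(sample_meta)) {
    files["sample_meta"] <- file.path(dir, "sample_meta.csv")
    sm <- sample_meta
    sm$CollectionDate <- format(as.Date(sm$CollectionDate), "%Y-%m-%d")
    data.table::fwrite(sm, files["sample_meta"], quote = FALSE)
  }
  if (!is.null(truth)) {
    files["truth"] <- file.path(dir, "truth.json")
    write_ground_truth(truth, files["truth"])
  }
  invisible(files)
}

write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read fixture files back into memory
#'
#' Inverse of [write_fixture()].
#'
#' @param dir fixture directory.
#' @param scale scale of the stored expression values.
#' @return list with `expression`, `diagnoses`, `sample_meta` (or `NULL`),
#'   `truth` (or `NULL`).
#' @export
read_fixture <- function(dir, scale = "log2") {
  expr <- read_expression(file.path(dir, "expression.csv"), scale)
  diag <- read_diagnosis(file.path(dir, "diagnosis.csv"))
  smp <- file.path(dir, "sample_meta.csv")
  meta <- if (file.exists(smp)) read_sample_meta(smp) else NULL
  tjp <- file.path(dir, "truth.json")
  truth <- if (file.exists(tjp)) read_ground_truth(tjp) else NULL
  list(expression = expr, diagnoses = diag, sample_meta = meta, truth = truth)
}

read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_edges <- function(e, cols) {
    empty <- empty_edges()
    if ("r" %in% cols) empty$r <- numeric()
    if ("sign" %in% cols) empty$sign <- character()
    if (is.null(e)) return(empty)
    if (!is.data.frame(e)) {
      if (all(lengths(e) == 0)) return(empty)
      e <- as.data.frame(lapply(e, unlist), stringsAsFactors = FALSE)
    }
    if (!nrow(e)) return(empty)
    e <- e[, cols, drop = FALSE]
    if ("r" %in% cols) e$r <- as.numeric(e$r)
    e
  }
  de <- j$de_probes
  de <- if (is.null(de) || !length(de))
    data.frame(probe = character(), state = character(), shift = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  else as.data.frame(de, stringsAsFactors = FALSE)
  structure(list(
    de_probes = de,
    edges_by_state = lapply(j$edges_by_state, fix_edges,
                            cols = c("source", "target", "r")),
    consensus_gained = fix_edges(j$consensus_gained,
                                 c("source", "target", "sign")),
    consensus_lost = fix_edges(j$consensus_lost,
                               c("source", "target", "sign")),
    rewired_nodes = as.character(unlist(j$rewired_nodes))),
    class = "GroundTruth")
}

#' Canned validation scenario: a fully rewired hub
#'
#' Thirty probes, one hub (`P0001`) that shares an `r = 0.8` correlation
#' block with nine partners in the reference state and with two disjoint
#' sets of nine partners in the two condition states. Every co-expression
#' partner of the hub switches between states, so the hub is the planted
#' top-rewired node; two probes stay unstructured background.
#'
#' @param seed RNG seed.
#' @param n_per_state samples per state (default 150).
#' @param r block correlation target (default 0.8).
#' @return A `SimConfig`.
#' @export
demo_config_rewired_hub <- function(seed = 1L, n_per_state = 150L, r = 0.8) {
  p <- sprintf("P%04d", 1:30)
  sim_config(
    n_probes = 30, n_per_state = n_per_state, seed = seed,
    blocks = list(
      corr_block(c(p[1], p[2:10]),  NC  = r),
      corr_block(c(p[1], p[11:19]), MCI = r),
      corr_block(c(p[1], p[20:28]), AD  = r)))
}

#' Canned validation scenario: consensus edges by correlation sign flip
#'
#' One 30-probe block correlated at `|r| = 0.8` in every state. In the
#' reference state all factor loadings are positive, so all pairs are
#' positively co-expressed. In both condition states the loadings of the
#' second half of the probes are negated, so every cross-half pair flips to
#' correlation `-0.8`: those pairs are lost from the positive-correlation
#' network and gained in the negative-correlation network, consistently in
#' both conditions. Because every pair carries planted structure, the
#' scenario has a fully determined consensus ground truth.
#'
#' @inheritParams demo_config_rewired_hub
#' @return A `SimConfig`.
#' @export
demo_config_sign_flip <- function(seed = 1L, n_per_state = 150L, r = 0.8) {
  p <- sprintf("P%04d", 1:30)
  neg <- p[16:30]
  sim_config(
    n_probes = 30, n_per_state = n_per_state, seed = seed,
    blocks = list(
      corr_block(p, NC = r,
                 MCI = list(r = r, neg = neg),
                 AD  = list(r = r, neg = neg))))
}

#' Canned validation scenario: a small end-to-end study
#'
#' Forty probes, fifteen samples per state. Probes `P0001`-`P0020` carry
#' log2 mean shifts in MCI and AD (alternating up/down, magnitudes 0.8-1.5)
#' so they pass the ANOVA stage; two correlation blocks among them give the
#' networks structure: one block whose correlations flip sign in the
#' condition states and one block present only in MCI and AD. Probes
#' `P0021`-`P0040` are unstructured background. This is the configuration
#' behind the fixture shipped under `inst/extdata/fixture_small/`.
#'
#' @param seed RNG seed.
#' @return A `SimConfig`.
#' @export
demo_config_small_study <- function(seed = 42L) {
  p <- sprintf("P%04d", 1:40)
  de <- do.call(rbind, lapply(1:20, function(i) {
    shift <- (0.8 + 0.7 * ((i - 1) %% 6) / 5) * (if (i %% 2) 1 else -1)
    data.frame(probe = p[i], state = c("MCI", "AD"),
               shift = c(0.7 * shift, shift), stringsAsFactors = FALSE)
  }))
  sim_config(
    n_probes = 40, n_per_state = 15, seed = seed, de_probes = de,
    blocks = list(
      corr_block(p[1:6], NC = 0.8,
                 MCI = list(r = 0.8, neg = p[4:6]),
                 AD  = list(r = 0.8, neg = p[4:6])),
      corr_block(p[7:12], MCI = 0.8, AD = 0.8)))
}
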