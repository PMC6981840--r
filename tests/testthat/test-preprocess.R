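make_meta <- function(sample, subject, date) {
  data.frame(SampleID = sample, SubjectID = subject,
             CollectionDate = as.Date(date), stringsAsFactors = FALSE)
}
make_recs <- function(subject, dates, labels) {
  data.frame(SubjectID = subject, ExamDate = as.Date(dates),
             Diagnosis = labels, stringsAsFactors = FALSE)
}

test_that("diagnosis assignment picks the nearest exam date", {
  meta <- make_meta("s1", "A", "2010-05-01")
  recs <- make_recs("A", c("2010-04-01", "2010-07-01"), c("MCI", "AD"))
  a <- assign_diagnosis(meta, recs)
  expect_identical(a$Diagnosis, "MCI")   # 30 days beats 61
  expect_identical(a$days_offset, 30L)

  ## a single record wins regardless of distance
  b <- assign_diagnosis(meta, make_recs("A", "2002-01-01", "AD"))
  expect_identical(b$Diagnosis, "AD")

  ## equidistant records: the earlier one wins
  recs3 <- make_recs("A", c("2010-04-01", "2010-05-31"), c("MCI", "AD"))
  expect_identical(assign_diagnosis(meta, recs3)$Diagnosis, "MCI")
})

test_that("samples without diagnosis records are dropped with a warning", {
  meta <- make_meta(c("s1", "s2"), c("A", "B"), c("2010-01-01", "2010-01-02"))
  recs <- make_recs("A", "2010-01-05", "NC")
  expect_warning(a <- assign_diagnosis(meta, recs), "dropped")
  expect_identical(a$SampleID, "s1")
})

test_that("empty tables and bad dates are rejected with context", {
  meta <- make_meta("s1", "A", "2010-01-01")
  expect_error(assign_diagnosis(meta, make_recs(character(0), as.Date(character(0)), character(0))),
               "empty")
  bad <- data.frame(SubjectID = "A", ExamDate = "not-a-date",
                    Diagnosis = "NC")
  expect_error(assign_diagnosis(meta, bad), "row")
})

test_that("delog exponentiates, round-trips, and refuses linear input", {
  m <- matrix(c(0, 10, 3.25, -1), 2, 2,
              dimnames = list(c("P1", "P2"), c("a", "b")))
  x <- expression_matrix(m, "log2")
  lin <- delog(x)
  expect_identical(lin$scale, "linear")
  expect_identical(lin$values[1, 1], 1)      # 2^0
  expect_identical(lin$values[2, 1], 1024)   # 2^10
  expect_equal(relog(lin)$values, m)
  expect_error(delog(lin), "linear")
  expect_error(relog(x), "log2")
})

test_that("the variation/intensity filter applies the CV window and intensity fraction", {
  v <- rbind(P1 = c(200, 300, 250, 100),    # CV ~ 0.40 -> out
             P2 = c(1, 500, 1, 500),        # CV ~ 1.15, 50% > 100 -> in
             P3 = c(100, 100, 100, 100),    # CV = 0 -> out
             P4 = c(0, 0, 0, 0))            # mean 0: flagged, out
  colnames(v) <- paste0("s", 1:4)
  res <- filter_variation(expression_matrix(v, "linear"))
  expect_identical(unname(res$keep), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$stats$cv[1], sd(v[1, ]) / mean(v[1, ]))
  expect_true(res$stats$flagged[4])
  expect_error(filter_variation(expression_matrix(v, "log2")), "linear")
})

test_that("the intensity criterion is 'strictly greater' in '20% or more' samples", {
  v <- rbind(P1 = c(50, 60, 120, 80, 90))   # exactly 1/5 above 100
  colnames(v) <- paste0("s", 1:5)
  res <- filter_variation(expression_matrix(v, "linear"))
  expect_identical(res$stats$frac_above_cut, 0.2)
  ## boundary: a value exactly at the cut does not count
  v2 <- rbind(P1 = c(50, 60, 100, 80, 90))
  colnames(v2) <- paste0("s", 1:5)
  expect_identical(filter_variation(expression_matrix(v2, "linear"))$stats$frac_above_cut, 0)
})

test_that("ANOVA filter keeps strong group differences and is calibrated under the null", {
  lab <- state_labels(20)
  set.seed(1)
  strong <- matrix(c(rnorm(20, 100, 10), rnorm(20, 500, 10),
                     rnorm(20, 1000, 10)), 1, dimnames = list("P1", NULL))
  colnames(strong) <- paste0("s", 1:60)
  res <- filter_anova(expression_matrix(strong, "linear"), lab, 0.1)
  expect_true(res$keep[["P1"]])
  expect_lt(res$stats$anova_p, 1e-10)

  flat <- matrix(rep(100, 60), 1, dimnames = list("P1", paste0("s", 1:60)))
  resf <- filter_anova(expression_matrix(flat, "linear"), lab, 0.1)
  expect_identical(resf$stats$anova_p, 1)
  expect_true(resf$stats$flagged)

  ## null calibration: ~10% retention at alpha = 0.1
  set.seed(42)
  nullm <- matrix(rnorm(400 * 30, 100, 10), 400,
                  dimnames = list(sprintf("P%03d", 1:400), paste0("s", 1:30)))
  resn <- filter_anova(expression_matrix(nullm, "linear"), state_labels(10), 0.1)
  expect_gt(mean(resn$keep), 0.1 - 2.576 * sqrt(0.09 / 400))
  expect_lt(mean(resn$keep), 0.1 + 2.576 * sqrt(0.09 / 400))
})

test_that("the cascade matches a naive per-probe oracle on random matrices", {
  lab <- state_labels(10)
  for (seed in 1:10) {
    set.seed(seed)
    x <- random_log2_matrix(60, 30)
    got <- run_filter_cascade(x, lab)
    expect_identical(probe_ids(got$data),
                     oracle_cascade(x$values, lab))
    counts <- attr(got$report, "counts")
    expect_identical(unname(counts["n_stage2"]),
                     length(probe_ids(got$data)))
    ## stage-2 survivors are a subset of stage-1 survivors
    expect_true(all(!got$report$pass_stage2 | got$report$pass_stage1))
  }
})

test_that("vacuous filter settings keep every probe and widening never shrinks the set", {
  lab <- state_labels(8)
  set.seed(5)
  x <- random_log2_matrix(40, 24)
  cfg_all <- filter_config(cv_min = 1e-12, cv_max = Inf,
                           intensity_cut = 1e-12, min_frac = 1e-12,
                           anova_alpha = 1 - 1e-12)
  got <- run_filter_cascade(x, lab, cfg_all)
  expect_identical(probe_ids(got$data), probe_ids(x))

  narrow <- filter_config(cv_min = 0.7, cv_max = 2, intensity_cut = 150,
                          min_frac = 0.4)
  wide <- filter_config(cv_min = 0.3, cv_max = 10, intensity_cut = 100,
                        min_frac = 0.2)
  lin <- delog(x)
  sn <- filter_variation(lin, narrow)
  sw <- filter_variation(lin, wide)
  expect_true(all(names(sn$keep)[sn$keep] %in% names(sw$keep)[sw$keep]))
})

test_that("a cascade built to pass exactly 50 planted probes passes exactly 50", {
  ## 50 planted probes: strong state effect + CV inside the window;
  ## 30 background probes: tiny CV, certain to fail stage 1
  set.seed(77)
  n <- 20; lab <- state_labels(n)
  planted <- t(sapply(1:50, function(i)
    c(rnorm(n, 7, 1), rnorm(n, 9, 1), rnorm(n, 11, 1))))
  background <- matrix(rnorm(30 * 3 * n, 7, 0.01), 30)
  v <- rbind(planted, background)
  dimnames(v) <- list(sprintf("P%03d", 1:80), sprintf("s%02d", 1:60))
  got <- run_filter_cascade(expression_matrix(v, "log2"), lab)
  expect_identical(nrow(got$data$values), 50L)
  expect_identical(probe_ids(got$data), sprintf("P%03d", 1:50))
})

test_that("zero survivors is a warning, not a crash, and scale misuse errors", {
  lab <- state_labels(4)
  v <- matrix(rnorm(5 * 12, 7, 0.001), 5,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:12)))
  x <- expression_matrix(v, "log2")
  expect_warning(got <- run_filter_cascade(x, lab), "no probes")
  expect_identical(nrow(got$data$values), 0L)
  expect_error(run_filter_cascade(delog(x), lab), "log2")
})
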