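test_that("identical networks give all-zero scores; a 1-of-3 edge scores 2/3 at both ends", {
  base <- net_from_pairs(list(c("N01", "N02"), c("N03", "N04")))
  same <- rewiring_scores(list(base, base, base))
  expect_true(all(same$score == 0))

  only1 <- rewiring_scores(list(
    net_from_pairs(list(c("N01", "N02"))), net_from_pairs(list()),
    net_from_pairs(list())))
  expect_equal(only1$score[only1$node == "N01"], 2 / 3, tolerance = 1e-12)
  expect_equal(only1$score[only1$node == "N02"], 2 / 3, tolerance = 1e-12)
  expect_true(all(only1$score[!only1$node %in% c("N01", "N02")] == 0))

  ## 2-of-3 pattern also contributes exactly 2/3 per slot
  only2 <- rewiring_scores(list(
    net_from_pairs(list(c("N01", "N02"))),
    net_from_pairs(list(c("N01", "N02"))), net_from_pairs(list())))
  expect_equal(only2$score[only2$node == "N01"], 2 / 3, tolerance = 1e-12)
})

test_that("scores add over independent adjacency slots (5 slots -> 10/3)", {
  ## N01 connected to five partners, each edge present in exactly one state
  partners <- sprintf("N%02d", 2:6)
  st <- list(list(), list(), list())
  for (i in seq_along(partners))
    st[[(i %% 3) + 1]] <- c(st[[(i %% 3) + 1]],
                            list(c("N01", partners[i])))
  tab <- rewiring_scores(lapply(st, net_from_pairs))
  expect_equal(tab$score[tab$node == "N01"], 10 / 3, tolerance = 1e-12)
})

test_that("rewiring scores equal the naive centroid-distance oracle on random triples", {
  set.seed(61)
  for (i in 1:30) {
    nodes <- sprintf("V%02d", 1:sample(4:10, 1))
    nets <- lapply(c("NC", "MCI", "AD"), function(s)
      random_network(nodes, p_edge = runif(1, 0.1, 0.6), state = s))
    got <- rewiring_scores(nets)
    want <- oracle_rewiring(nets)
    expect_equal(setNames(got$score, got$node), want, tolerance = 1e-12)
  }
})

test_that("scores are invariant under state permutation and node sets must match", {
  set.seed(62)
  nodes <- sprintf("V%02d", 1:8)
  nets <- lapply(c("NC", "MCI", "AD"), function(s)
    random_network(nodes, p_edge = 0.4, state = s))
  a <- rewiring_scores(nets)
  b <- rewiring_scores(nets[c(3, 1, 2)])
  expect_equal(setNames(a$score, a$node), setNames(b$score, b$node),
               tolerance = 1e-12)
  bad <- random_network(c(nodes[-1], "OTHER"), state = "AD")
  expect_error(rewiring_scores(list(nets[[1]], bad)), "identical node set")
  expect_warning(rewiring_scores(nets[1]), "single network")
})

test_that("weighted mode and score variants behave sensibly", {
  n1 <- net_from_pairs(list(c("N01", "N02")))
  n1$edges$weight <- 0.9
  n0 <- net_from_pairs(list())
  wt <- rewiring_scores(list(n1, n0, n0), mode = "weighted")
  expect_equal(wt$score[wt$node == "N01"], 0.9^2 * 2 / 3, tolerance = 1e-12)

  dg <- rewiring_scores(list(n1, n0, n0), variant = "degree")
  ## raw 2/3 divided by mean degree 1/3 -> 2
  expect_equal(dg$score[dg$node == "N01"], 2, tolerance = 1e-12)

  us <- rewiring_scores(list(n1, n0, n0), variant = "unsquared")
  expect_equal(us$score[us$node == "N01"], 2 / 3 + 1 / 3 + 1 / 3,
               tolerance = 1e-12)
})

test_that("top_rewired applies the cutoff with deterministic ordering", {
  tab <- data.frame(node = c("a", "b", "c", "d"),
                    score = c(8.33, 5.67, 4.0, 5.67))
  got <- top_rewired(tab, 5)
  expect_identical(got$node, c("a", "b", "d"))  # tie b/d broken by ID
  expect_identical(top_rewired(tab, 0)$node, c("a", "b", "d", "c"))
  zero <- data.frame(node = letters[1:3], score = rep(0, 3))
  expect_identical(nrow(top_rewired(zero, 5)), 0L)
})

test_that("the rewiring report carries both sign classes with the cutoff applied", {
  pos <- data.frame(node = c("a", "b"), score = c(9, 3))
  neg <- data.frame(node = c("a", "b"), score = c(1, 2))
  rep1 <- rewiring_report(pos, neg, cutoff = 5)
  expect_identical(rep1$positive$node, "a")
  expect_identical(nrow(rep1$negative), 0L)
  rep0 <- rewiring_report(pos, neg, cutoff = 0)
  expect_identical(nrow(rep0$positive), 2L)
})

test_that("consensus differential follows the all-conditions rule", {
  ref <- net_from_pairs(list(c("N01", "N02"), c("N03", "N04")), state = "NC")
  mci <- net_from_pairs(list(c("N01", "N02"), c("N05", "N06")), state = "MCI")
  ad <- net_from_pairs(list(c("N05", "N06"), c("N03", "N04")), state = "AD")
  d <- consensus_differential(ref, list(mci, ad))
  ## N05-N06 absent in NC, present in both conditions -> gained
  expect_identical(d$gained$source, "N05")
  ## N01-N02: lost in AD only -> neither; N03-N04: lost in MCI only -> neither
  expect_identical(nrow(d$lost), 0L)
  expect_identical(d$reference, "NC")
  expect_setequal(d$conditions, c("MCI", "AD"))
})

test_that("consensus output equals brute-force set algebra on random triples", {
  set.seed(63)
  for (i in 1:30) {
    nodes <- sprintf("V%02d", 1:8)
    ref <- random_network(nodes, p_edge = 0.35, state = "NC")
    conds <- lapply(c("MCI", "AD"), function(s)
      random_network(nodes, p_edge = 0.35, state = s))
    got <- consensus_differential(ref, conds)
    want <- oracle_consensus(ref, conds)
    expect_equal(got$gained, want$gained, ignore_attr = TRUE)
    expect_equal(got$lost, want$lost, ignore_attr = TRUE)
    key <- function(d) paste(d$source, d$target)
    expect_length(intersect(key(got$gained), key(got$lost)), 0)
    ## invariant to condition order
    got2 <- consensus_differential(ref, rev(conds))
    expect_identical(got$gained, got2$gained)
    expect_identical(got$lost, got2$lost)
  }
})

test_that("consensus validates its inputs", {
  ref <- net_from_pairs(list(c("N01", "N02")), state = "NC")
  neg <- net_from_pairs(list(c("N01", "N02")), sign = "negative")
  expect_error(consensus_differential(ref, list()), "at least one")
  expect_error(consensus_differential(ref, list(neg)), "sign")
  t03 <- net_from_pairs(list(c("N01", "N02")), threshold = 0.3)
  expect_error(consensus_differential(ref, list(t03)), "threshold")
})

test_that("a planted fully-rewired hub is ranked first", {
  sim <- simulate_expression(demo_config_rewired_hub(seed = 5))
  nets <- build_state_networks(delog(sim$expression), state_labels(150),
                               thresholds = 0.1)
  tab <- rewiring_scores(nets$networks[["0.1"]][["positive"]])
  expect_identical(tab$node[tab$rank == 1], sim$truth$rewired_nodes)
})

test_that("differential networks export with change annotations", {
  ref <- net_from_pairs(list(c("N01", "N02")), state = "NC")
  mci <- net_from_pairs(list(c("N03", "N04")), state = "MCI")
  ad <- net_from_pairs(list(c("N03", "N04")), state = "AD")
  d <- consensus_differential(ref, list(mci, ad))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_differential(d, f, "table")
  out <- read.delim(f)
  expect_setequal(out$change, c("gained", "lost"))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_differential(d, sif, "sif")
  expect_length(grep("\t(gained|lost)\t", readLines(sif)), 2L)
})
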