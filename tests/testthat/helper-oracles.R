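## Independent oracles and small fixture builders used across the suite.
## Oracles are deliberately naive (loops, closed forms) and share no code
## with the implementation paths they check.

## closed-form one-way fixed-effects ANOVA p-value
oracle_anova_p <- function(y, g) {
  g <- as.factor(g)
  k <- nlevels(g); N <- length(y)
  m <- mean(y)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    yi <- y[g == lev]
    ssb <- ssb + length(yi) * (mean(yi) - m)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  if (ssw == 0) return(if (ssb == 0) 1 else 0)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  stats::pf(f, k - 1, N - k, lower.tail = FALSE)
}

## naive per-probe recomputation of the whole filter cascade
oracle_cascade <- function(log2_values, labels, cv_min = 0.7, cv_max = 10,
                           cut = 100, min_frac = 0.2, alpha = 0.1) {
  lin <- 2^log2_values
  survivors <- character(0)
  for (p in rownames(lin)) {
    y <- lin[p, ]
    mu <- mean(y)
    if (mu == 0) next
    cv <- sd(y) / mu
    frac <- sum(y > cut) / length(y)
    if (!(cv >= cv_min && cv <= cv_max && frac >= min_frac)) next
    if (oracle_anova_p(y, labels) < alpha) survivors <- c(survivors, p)
  }
  survivors
}

## naive sort/adjust/unsort Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, p[o[i]] * m / i)
    adj[o[i]] <- cur
  }
  adj
}

## two-loop Pearson correlation matrix
oracle_pearson <- function(v) {
  n <- nrow(v)
  r <- diag(1, n)
  dimnames(r) <- list(rownames(v), rownames(v))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- v[i, ]; y <- v[j, ]
    r[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  r
}

## naive per-node centroid-distance rewiring score over edge-set lists
oracle_rewiring <- function(networks) {
  nodes <- networks[[1]]$nodes
  S <- length(networks)
  has_edge <- function(nw, a, b) {
    any(nw$edges$source == min(a, b) & nw$edges$target == max(a, b))
  }
  scores <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) for (u in nodes) {
    if (u == v) next
    slot <- vapply(networks, has_edge, logical(1), a = v, b = u)
    cen <- mean(slot)
    scores[v] <- scores[v] + sum((as.numeric(slot) - cen)^2)
  }
  scores
}

## brute-force consensus gained/lost by enumerating all node pairs
oracle_consensus <- function(reference, conditions) {
  nodes <- sort(reference$nodes)
  has_edge <- function(nw, a, b)
    any(nw$edges$source == a & nw$edges$target == b)
  gained <- lost <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    a <- nodes[i]; b <- nodes[j]
    in_ref <- has_edge(reference, a, b)
    in_conds <- vapply(conditions, has_edge, logical(1), a = a, b = b)
    if (!in_ref && all(in_conds)) gained[[length(gained) + 1]] <- c(a, b)
    if (in_ref && !any(in_conds)) lost[[length(lost) + 1]] <- c(a, b)
  }
  tod <- function(l) if (!length(l))
    data.frame(source = character(), target = character(),
               stringsAsFactors = FALSE)
  else {
    m <- do.call(rbind, l)
    d <- data.frame(source = m[, 1], target = m[, 2],
                    stringsAsFactors = FALSE)
    d[order(d$source, d$target), , drop = FALSE]
  }
  list(gained = tod(gained), lost = tod(lost))
}

## random SignedNetwork on a given node set (for structural/oracle tests)
random_network <- function(nodes, p_edge = 0.3, sign = "positive",
                           threshold = 0.1, state = "S") {
  pairs <- t(combn(sort(nodes), 2))
  keep <- runif(nrow(pairs)) < p_edge
  w <- runif(sum(keep), threshold + 1e-6, 1)
  if (sign == "negative") w <- -w
  edges <- data.frame(source = pairs[keep, 1], target = pairs[keep, 2],
                      weight = w, stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  coexdiff:::signed_network(nodes, edges, sign, threshold, state)
}

## small log2 expression matrix with random values
random_log2_matrix <- function(n_probes, n_samples, mean = 7, sd = 1.5) {
  m <- matrix(rnorm(n_probes * n_samples, mean, sd), n_probes,
              dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(m, "log2")
}

state_labels <- function(n_per_state, states = c("NC", "MCI", "AD")) {
  factor(rep(states, each = n_per_state), levels = states)
}

## hand-built SignedNetwork from a list of node pairs
net_from_pairs <- function(pairs, nodes = sprintf("N%02d", 1:6),
                           sign = "positive", threshold = 0.1, state = "S") {
  edges <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    d <- data.frame(source = pmin(m[, 1], m[, 2]),
                    target = pmax(m[, 1], m[, 2]), stringsAsFactors = FALSE)
    d$weight <- rep(0.5, nrow(d))
    d[order(d$source, d$target), ]
  } else data.frame(source = character(), target = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  coexdiff:::signed_network(nodes, edges, sign, threshold, state)
}
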