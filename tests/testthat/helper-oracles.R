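# Independent brute-force oracles used to cross-check the implementation.
# Deliberately naive: enumeration, loops and repeated recomputation only.

# Exact one-sided signed-rank p-value by enumerating all 2^n sign
# assignments (feasible for n <= 12).
oracle_signed_rank_p <- function(scores, tau) {
  d <- scores[!is.na(scores)] - tau
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% rk)
  mean(ws >= w)
}

# Row-by-row scan for the expressed-everywhere filter.
oracle_expressed <- function(p, alpha) {
  keep <- character(0)
  for (g in rownames(p)) {
    all_in <- TRUE
    for (s in colnames(p)) {
      if (is.na(p[g, s]) || p[g, s] >= alpha) all_in <- FALSE
    }
    if (all_in) keep <- c(keep, g)
  }
  keep
}

# Threshold scan for the stable set (or-combination over scopes).
oracle_stable_set <- function(stats, universe, cutoffs) {
  keep <- character(0)
  for (g in universe) {
    ok <- FALSE
    for (sc in names(cutoffs)) {
      cv <- stats$cv[stats$partition == sc & stats$gene_id == g]
      if (length(cv) == 1 && !is.na(cv) && cv < cutoffs[[sc]]) ok <- TRUE
    }
    if (ok) keep <- c(keep, g)
  }
  keep
}

# Pairwise variation straight from the definition.
oracle_v <- function(mat, j, k) {
  r <- log2(mat[j, ] / mat[k, ])
  stats::sd(r[!is.na(r)])
}

# M value by direct enumeration over the other genes.
oracle_m <- function(mat, gene) {
  others <- setdiff(rownames(mat), gene)
  mean(sapply(others, function(k) oracle_v(mat, gene, k)))
}

# Full stepwise exclusion by recomputing every M from scratch each round.
oracle_stepwise <- function(mat) {
  remaining <- rownames(mat)
  order_out <- character(0)
  m_out <- numeric(0)
  while (length(remaining) > 2) {
    m <- sapply(remaining, function(g)
      mean(sapply(setdiff(remaining, g), function(k)
        oracle_v(mat, g, k))))
    worst <- sort(names(m)[m == max(m)])[1]
    order_out <- c(order_out, worst)
    m_out <- c(m_out, unname(m[worst]))
    remaining <- setdiff(remaining, worst)
  }
  final <- sort(remaining)
  list(order = c(order_out, final),
       m = c(m_out, rep(oracle_v(mat, final[1], final[2]), 2)))
}

# V_{n/n+1} series from explicit geometric means.
oracle_v_series <- function(mat, stability_order) {
  g <- nrow(mat)
  sapply(2:(g - 1), function(n) {
    top_n <- stability_order[1:n]
    top_n1 <- stability_order[1:(n + 1)]
    nf_n <- apply(mat[top_n, , drop = FALSE], 2, function(x)
      prod(x)^(1 / length(x)))
    nf_n1 <- apply(mat[top_n1, , drop = FALSE], 2, function(x)
      prod(x)^(1 / length(x)))
    stats::sd(log2(nf_n / nf_n1))
  })
}

# Random positive relative-quantity matrix.
random_quantities <- function(g, s, seed) {
  set.seed(seed)
  mat <- matrix(2 ^ rnorm(g * s, 0, 1), g, s,
                dimnames = list(sprintf("g%02d", 1:g),
                                sprintf("s%02d", 1:s)))
  mat
}

# Small metadata table builder for unit tests.
make_meta <- function(groups) {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(sample_id = g$samples,
               study_id = if (is.null(g$study)) "study01" else g$study,
               replicate_group = g$group,
               partition = g$partition,
               stringsAsFactors = FALSE)
  }))
}
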