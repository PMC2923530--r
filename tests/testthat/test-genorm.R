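# geNORM engine: delta-Ct transform, pairwise variation, M values,
# stepwise exclusion, normalization factors and the V series.

test_that("delta-Ct transform maps the lowest Ct to 1", {
  ct <- rbind(g1 = c(20, 21, 23))
  colnames(ct) <- paste0("s", 1:3)
  expect_equal(unname(ct_to_relative_quantity(ct)["g1", ]),
               c(1, 0.5, 0.125))
  ct2 <- rbind(g1 = c(25, 25, 25), g2 = c(18, 19.5, NA))
  colnames(ct2) <- paste0("s", 1:3)
  q <- ct_to_relative_quantity(ct2, efficiency = c(g1 = 2, g2 = 1.9))
  expect_equal(unname(q["g1", ]), c(1, 1, 1))
  expect_equal(unname(q["g2", 1:2]), c(1, 1.9^-1.5))
  expect_true(is.na(q["g2", 3]))   # not measured propagates
  expect_error(ct_to_relative_quantity(rbind(g1 = c(20, NA, NA))),
               "fewer than 2")
})

test_that("pairwise variation is the SD of log2 ratios", {
  expect_equal(pairwise_variation(c(2, 4, 8), c(1, 2, 4)), 0)
  expect_equal(pairwise_variation(c(1, 2), c(1, 1)), sqrt(0.5))
  # symmetry and invariance to per-sample scaling of both genes
  set.seed(5)
  a <- 2^rnorm(6); b <- 2^rnorm(6); s <- rexp(6)
  expect_equal(pairwise_variation(a, b), pairwise_variation(b, a))
  expect_equal(pairwise_variation(a * s, b * s), pairwise_variation(a, b))
  expect_error(pairwise_variation(c(1, NA, 2), c(NA, 1, NA)),
               "fewer than 2 common")
})

test_that("M values match direct enumeration over pairwise SDs", {
  mat <- random_quantities(4, 5, seed = 21)
  m <- stability_M(mat)
  for (g in rownames(mat)) expect_equal(unname(m[g]), oracle_m(mat, g))
  # three proportional genes: all M = 0
  prop <- rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(0.5, 1, 2))
  colnames(prop) <- paste0("s", 1:3)
  expect_equal(unname(stability_M(prop)), c(0, 0, 0))
})

test_that("adding a variable gene never lowers another gene's M beyond it", {
  set.seed(33)
  for (rep in 1:10) {
    mat <- random_quantities(4, 6, seed = 100 + rep)
    extra <- matrix(2^rnorm(6, 0, 4), 1, 6,
                    dimnames = list("zz_new", colnames(mat)))
    big <- rbind(mat, extra)
    m_old <- stability_M(mat)
    m_new <- stability_M(big)
    for (g in rownames(mat)) {
      v_new <- pairwise_variation(big[g, ], big["zz_new", ])
      if (v_new >= m_old[g]) {
        expect_gte(m_new[g], m_old[g] - 1e-12)
      } else {
        expect_equal(unname(m_new[g]),
                     (3 * unname(m_old[g]) + v_new) / 4)
      }
    }
  }
})

test_that("stepwise ranking matches brute-force recomputation (G<=6, S<=8)", {
  cases <- expand.grid(g = 3:6, s = c(3, 5, 8))
  for (i in seq_len(nrow(cases))) {
    mat <- random_quantities(cases$g[i], cases$s[i], seed = 500 + i)
    fit <- genorm(mat)
    orc <- oracle_stepwise(mat)
    expect_identical(fit$ranking$gene_id, orc$order)
    expect_equal(fit$ranking$m_at_removal, orc$m)
    expect_equal(unname(fit$v_series),
                 oracle_v_series(mat, fit$stability_order))
  }
})

test_that("a planted noisy gene is excluded first", {
  set.seed(61)
  base <- 2^rnorm(8, 0, 0.1)
  mat <- rbind(g1 = base * 2^rnorm(8, 0, 0.05),
               g2 = base * 2^rnorm(8, 0, 0.05),
               g3 = base * 2^rnorm(8, 0, 0.05),
               g4 = base * 2^rnorm(8, 0, 0.05),
               g5 = base * 2^rnorm(8, 0, 0.05),
               noisy = base * 2^rnorm(8, 0, 2))
  colnames(mat) <- paste0("s", 1:8)
  fit <- genorm(mat)
  expect_identical(fit$ranking$gene_id[1], "noisy")
})

test_that("proportional genes tie out deterministically with M = 0", {
  prop <- rbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(4, 8, 16))
  colnames(prop) <- paste0("s", 1:3)
  fit <- genorm(prop)
  expect_equal(fit$ranking$m_at_removal, c(0, 0, 0))
  expect_identical(fit$ranking$gene_id[1], "a")   # lexicographic tie rule
  # final pair shares one M equal to its own pairwise variation
  last <- fit$ranking[fit$ranking$step == max(fit$ranking$step), ]
  expect_identical(nrow(last), 2L)
  expect_equal(last$m_at_removal[1], last$m_at_removal[2])
  expect_equal(last$m_at_removal[1],
               pairwise_variation(prop[last$gene_id[1], ],
                                  prop[last$gene_id[2], ]))
  expect_equal(fit$recommended_n, 2L)
  expect_equal(unname(fit$v_series), 0)
})

test_that("ranking is invariant under per-sample global scaling", {
  mat <- random_quantities(5, 6, seed = 77)
  s <- rexp(6, 1 / 3)
  fit1 <- genorm(mat)
  fit2 <- genorm(sweep(mat, 2, s, `*`))
  expect_identical(fit1$ranking$gene_id, fit2$ranking$gene_id)
  expect_equal(fit1$ranking$m_at_removal, fit2$ranking$m_at_removal)
  expect_equal(fit1$v_series, fit2$v_series)
})

test_that("normalization factors are geometric means with the scaling law", {
  mat <- rbind(g1 = c(4, 1, 9), g2 = c(1, 1, 1), g3 = c(2, 8, 3))
  colnames(mat) <- paste0("s", 1:3)
  expect_equal(unname(normalization_factor(mat, c("g1", "g2"))),
               c(2, 1, 3))
  expect_equal(unname(normalization_factor(mat, c("g1", "g2", "g3"))),
               apply(mat, 2, function(x) exp(mean(log(x))), simplify = TRUE),
               ignore_attr = TRUE)
  # multiplying one chosen gene by c scales all factors by c^(1/n)
  mat2 <- mat; mat2["g1", ] <- mat2["g1", ] * 8
  expect_equal(normalization_factor(mat2, c("g1", "g2")),
               normalization_factor(mat, c("g1", "g2")) * 8^(1 / 2))
})

test_that("V-series threshold logic flags never-met thresholds", {
  mat <- random_quantities(5, 6, seed = 91)
  fit <- genorm(mat, v_threshold = 1e-12)
  expect_false(fit$threshold_met)
  expect_identical(fit$recommended_n, nrow(mat) - 1L)
})

test_that("a 5x-noise planted gene ranks last in >= 95% of 200 replicates", {
  set.seed(1234)
  hits <- 0L
  for (rep in 1:200) {
    base <- rnorm(8, 0, 0.3)
    l2 <- rbind(matrix(rep(base, each = 5), 5, 8) +
                  matrix(rnorm(40, 0, 0.15), 5, 8),
                base + rnorm(8, 0, 0.75))
    rownames(l2) <- c(paste0("g", 1:5), "unstable")
    colnames(l2) <- paste0("s", 1:8)
    fit <- genorm(2^l2)
    if (fit$ranking$gene_id[1] == "unstable") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})
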