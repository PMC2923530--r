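# Partitioned CV statistics and the stable-gene selection logic.

# metadata with 2 samples per scope-relevant partition
stab_meta <- function() {
  make_meta(list(
    list(samples = c("d1", "d2"), group = "leaf", partition = "development"),
    list(samples = c("a1", "a2"), group = "cold", partition = "abiotic",
         study = "study02"),
    list(samples = c("b1", "b2"), group = "fungus", partition = "biotic",
         study = "study03"),
    list(samples = c("h1", "h2"), group = "iaa", partition = "hormone",
         study = "study04")))
}

test_that("partition stats reproduce CV = SD/mean on constructed genes", {
  meta <- stab_meta()
  # alternating-sign construction with exact mean m and sample SD s over
  # the 8 entire-scope samples
  mk <- function(m, s, n = 8) rep(m + c(1, -1) * s * sqrt((n - 1) / n),
                                  n / 2)
  expr <- rbind(
    g1 = mk(991.9, 210.2),       # published nucleic-acid-binding row
    g2 = c(rep(10, 7), 8000),    # heavily skewed: CV exceeds 1
    g3 = rep(500, 8))            # constant gene
  colnames(expr) <- meta$sample_id
  st <- partition_stats(expr, meta, "entire")
  expect_equal(st$mean[1], 991.9)
  expect_equal(st$sd[1], 210.2)
  expect_identical(sprintf("%.2f", st$cv[1]), "0.21")
  expect_gt(st$cv[2], 1)
  # the published endo-1,4-beta-glucanase mean/SD pair also gives CV > 1
  expect_identical(sprintf("%.2f", 1063.3 / 900.7), "1.18")
  expect_equal(unlist(st[st$gene_id == "g3", c("mean", "sd", "cv")]),
               c(mean = 500, sd = 0, cv = 0))
})

test_that("scopes select the documented sample subsets", {
  meta <- stab_meta()
  expr <- matrix(1, 1, 8, dimnames = list("g1", meta$sample_id))
  # make the gene vary only in hormone samples: dev and stress CV stay 0
  expr[1, c("h1", "h2")] <- c(10, 30)
  dev <- partition_stats(expr, meta, "development")
  str <- partition_stats(expr, meta, "stress")
  ent <- partition_stats(expr, meta, "entire")
  expect_equal(dev$cv, 0)
  expect_equal(str$cv, 0)
  expect_gt(ent$cv, 0)   # hormone samples enter only the entire scope
})

test_that("CV is invariant under global positive rescaling", {
  meta <- stab_meta()
  set.seed(15)
  expr <- matrix(rexp(5 * 8, 1 / 1000), 5, 8,
                 dimnames = list(paste0("g", 1:5), meta$sample_id))
  for (sc in c("development", "stress", "entire")) {
    a <- partition_stats(expr, meta, sc)
    b <- partition_stats(expr * 7.3, meta, sc)
    expect_equal(a$cv, b$cv)
  }
})

test_that("zero-mean genes are flagged with undefined CV", {
  meta <- stab_meta()
  expr <- matrix(0, 1, 8, dimnames = list("g1", meta$sample_id))
  st <- partition_stats(expr, meta, "entire")
  expect_true(is.na(st$cv))
})

test_that("rank_by_cv sorts ascending with lexicographic tie-break", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"), partition = "entire",
                    mean = 1, sd = 1, cv = c(0.21, 0.60, 0.28),
                    stringsAsFactors = FALSE)
  expect_identical(rank_by_cv(tab, "entire"), c("g1", "g3", "g2"))
  tab$cv <- 0.3
  expect_identical(rank_by_cv(tab, "entire"), c("g1", "g2", "g3"))
  set.seed(31)
  big <- data.frame(gene_id = sprintf("g%03d", 1:100), partition = "entire",
                    mean = 1, sd = 1, cv = round(runif(100), 2),
                    stringsAsFactors = FALSE)
  expect_identical(rank_by_cv(big, "entire"),
                   big$gene_id[order(big$cv, big$gene_id)])
})

# random three-scope stability table over `n` genes
random_stab <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(c("development", "stress", "entire"), function(sc)
    data.frame(gene_id = sprintf("g%03d", 1:n), partition = sc,
               mean = 1000, sd = 1, cv = round(runif(n, 0, 0.8), 3),
               stringsAsFactors = FALSE)))
}

test_that("stable set equals the brute-force threshold scan", {
  for (seed in 1:5) {
    stab <- random_stab(40, seed)
    universe <- sprintf("g%03d", 1:40)
    sel <- select_stable(stab, universe,
                         selection_config(n_random_extra = 0))
    expect_identical(sel$stable_set,
                     oracle_stable_set(stab, universe,
                                       list(development = 0.35,
                                            stress = 0.35,
                                            entire = 0.35)))
  }
})

test_that("stable set is monotone in the CV cutoff", {
  stab <- random_stab(60, 9)
  universe <- sprintf("g%03d", 1:60)
  cfg1 <- selection_config(cv_cutoff_development = 0.2,
                           cv_cutoff_stress = 0.2, cv_cutoff_entire = 0.2,
                           n_random_extra = 0)
  cfg2 <- selection_config(cv_cutoff_development = 0.5,
                           cv_cutoff_stress = 0.5, cv_cutoff_entire = 0.5,
                           n_random_extra = 0)
  s1 <- select_stable(stab, universe, cfg1)$stable_set
  s2 <- select_stable(stab, universe, cfg2)$stable_set
  expect_true(all(s1 %in% s2))
})

test_that("selection picks are scope-ranked, tagged, disjoint and seeded", {
  stab <- random_stab(40, 3)
  universe <- sprintf("g%03d", 1:40)
  cfg <- selection_config(rng_seed = 77)
  sel <- select_stable(stab, universe, cfg)
  # chosen genes come from the stable set with exhaustive, exclusive tags
  expect_true(all(sel$chosen$gene_id %in% sel$stable_set))
  expect_false(anyDuplicated(sel$chosen$gene_id) > 0)
  expect_identical(as.vector(table(sel$chosen$provenance)[
    c("lowest-CV-stress", "lowest-CV-development", "lowest-CV-entire",
      "random-below-cutoff")]), c(2L, 2L, 3L, 4L))
  # stress picks are the two lowest stress CVs within the stable set
  cv_str <- with(stab[stab$partition == "stress", ],
                 setNames(cv, gene_id))[sel$stable_set]
  expect_identical(sel$chosen$gene_id[1:2],
                   names(sort(cv_str))[1:2])
  # determinism under a fixed seed
  sel2 <- select_stable(stab, universe, cfg)
  expect_identical(sel$chosen, sel2$chosen)

  # all-zero configuration leaves the stable set untouched, chooses nothing
  none <- select_stable(stab, universe,
                        selection_config(top_k_stress = 0,
                                         top_k_development = 0,
                                         top_k_entire = 0,
                                         n_random_extra = 0))
  expect_identical(nrow(none$chosen), 0L)
  expect_identical(none$stable_set, sel$stable_set)
})

test_that("an exhausted stable pool warns and returns what is available", {
  stab <- random_stab(4, 5)
  stab$cv <- 0.9
  stab$cv[stab$gene_id == "g001"] <- 0.1   # one stable gene only
  warns <- capture_warnings(
    sel <- select_stable(stab, sprintf("g%03d", 1:4), selection_config()))
  expect_true(any(grepl("exhausted", warns)))
  expect_identical(sel$stable_set, "g001")
  expect_lte(nrow(sel$chosen), 1L)
})
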