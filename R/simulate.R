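# Seeded generator of a miniature multi-study expression compendium with
# known ground truth: normalized expression matrix, probe-level PM/MM
# intensities, sample metadata and qPCR Ct tables. Intensities follow a
# log-normal model: log2 expression = gene baseline + per-group effect +
# per-study batch shift + Gaussian noise. Four planted gene classes make
# every pipeline stage testable: stable (low CV everywhere), responsive
# (large shifts in a random subset of groups across all partitions),
# tissue-absent (near-background in some groups) and housekeeping-like
# (moderate group-to-group wobble).

#' Simulation configuration
#'
#' Defaults describe a small but structurally faithful compendium: 8
#' studies, 16 replicate groups spanning the four partitions, 2-4
#' replicates per group, and 500 genes split across the four planted
#' classes.
#'
#' @param n_studies Number of studies (default 8); studies are allocated
#'   to partitions proportionally to group counts and each study hosts
#'   groups of a single partition, so batch effects are confounded with
#'   study as in real multi-lab compendia.
#' @param replicates_range Integer range (min, max) of biological
#'   replicates per group (default 2-4).
#' @param groups_per_partition Named counts of replicate groups for
#'   development/abiotic/biotic/hormone (default 6/5/3/2).
#' @param n_genes Number of genes (default 500).
#' @param class_fractions Named fractions for
#'   stable/responsive/tissue_absent/housekeeping_like (default
#'   0.1/0.4/0.2/0.3; must sum to 1).
#' @param base_log2_mean_range Range of per-gene baseline log2 expression
#'   (default 6-14).
#' @param stable_noise_sd_log2 Residual log2 noise SD (default 0.15).
#' @param responsive_effect_log2 Magnitude of the log2 shift a responsive
#'   gene shows in each affected group (default 2).
#' @param response_prob Probability that a responsive gene is shifted in
#'   any given group (default 0.5, applied in every partition: responsive
#'   genes model tissue- as well as treatment-regulated transcripts).
#' @param hk_wobble_sd_log2 SD of the per-group log2 wobble of
#'   housekeeping-like genes (default 0.4, "moderate variability").
#' @param batch_sd_log2 SD of the per-study batch shift (default 0.3).
#' @param absent_log2 Log2 level of a tissue-absent gene in its absent
#'   groups (default 0, i.e. near background).
#' @param probe_pairs PM/MM pairs per probeset (default 11, the
#'   Affymetrix convention).
#' @param probe_affinity_sd_log2 SD of the fixed per-probe log2 affinity
#'   (default 0.4).
#' @param probe_noise_sd_log2 SD of the multiplicative per-measurement
#'   probe noise (default 0.15).
#' @param background Additive optical/cross-hybridization background
#'   intensity entering PM and MM (default 50).
#' @param seed RNG seed (default 42).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 8L,
                              replicates_range = c(2L, 4L),
                              groups_per_partition = c(development = 6L,
                                                       abiotic = 5L,
                                                       biotic = 3L,
                                                       hormone = 2L),
                              n_genes = 500L,
                              class_fractions = c(stable = 0.1,
                                                  responsive = 0.4,
                                                  tissue_absent = 0.2,
                                                  housekeeping_like = 0.3),
                              base_log2_mean_range = c(6, 14),
                              stable_noise_sd_log2 = 0.15,
                              responsive_effect_log2 = 2,
                              response_prob = 0.5,
                              hk_wobble_sd_log2 = 0.4,
                              batch_sd_log2 = 0.3,
                              absent_log2 = 0,
                              probe_pairs = 11L,
                              probe_affinity_sd_log2 = 0.4,
                              probe_noise_sd_log2 = 0.15,
                              background = 50,
                              seed = 42L) {
  cfg <- list(n_studies = as.integer(n_studies),
              replicates_range = as.integer(replicates_range),
              groups_per_partition = groups_per_partition,
              n_genes = as.integer(n_genes),
              class_fractions = class_fractions,
              base_log2_mean_range = base_log2_mean_range,
              stable_noise_sd_log2 = stable_noise_sd_log2,
              responsive_effect_log2 = responsive_effect_log2,
              response_prob = response_prob,
              hk_wobble_sd_log2 = hk_wobble_sd_log2,
              batch_sd_log2 = batch_sd_log2,
              absent_log2 = absent_log2,
              probe_pairs = as.integer(probe_pairs),
              probe_affinity_sd_log2 = probe_affinity_sd_log2,
              probe_noise_sd_log2 = probe_noise_sd_log2,
              background = background,
              seed = seed)
  if (!setequal(names(cfg$groups_per_partition), PARTITIONS))
    stop_("groups_per_partition needs the four partitions: ",
          paste(PARTITIONS, collapse = ", "))
  if (any(cfg$groups_per_partition < 1L))
    stop_("every partition needs at least one replicate group")
  fr <- cfg$class_fractions
  if (!setequal(names(fr),
                c("stable", "responsive", "tissue_absent",
                  "housekeeping_like")))
    stop_("class_fractions needs stable/responsive/tissue_absent/",
          "housekeeping_like")
  if (abs(sum(fr) - 1) > 1e-8) stop_("class fractions must sum to 1")
  if (any(fr < 0)) stop_("class fractions must be nonnegative")
  stopifnot(cfg$probe_pairs >= 3L, cfg$stable_noise_sd_log2 >= 0,
            cfg$batch_sd_log2 >= 0, cfg$hk_wobble_sd_log2 >= 0,
            cfg$probe_noise_sd_log2 >= 0, cfg$n_studies >= 1L,
            length(cfg$replicates_range) == 2L,
            cfg$replicates_range[1L] >= 1L,
            cfg$replicates_range[1L] <= cfg$replicates_range[2L],
            cfg$n_genes >= 1L, cfg$background > 0)
  structure(cfg, class = "simulation_config")
}

# Largest-remainder allocation of `total` items proportional to `weights`
# (every positive weight gets at least one item when possible).
allocate_counts <- function(total, weights) {
  raw <- total * weights / sum(weights)
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Simulate a multi-study expression compendium
#'
#' Generates, under a fixed seed, the four linked artifacts every
#' pipeline stage consumes: a probe-level PM/MM table, a linear-scale
#' normalized expression matrix, sample metadata and a ground-truth
#' object recording each gene's planted class, per-group expected
#' expression and expressed/absent flags. Identical seeds give
#' bitwise-identical outputs.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_compendium`: `expr` (matrix), `probes`
#'   (long data.frame), `metadata` (data.frame), `truth` (list with
#'   `class`, `expected_log2`, `expressed`), `config`.
#' @export
simulate_compendium <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gp <- config$groups_per_partition[PARTITIONS]

    # studies per partition, groups round-robin over their studies
    st_counts <- allocate_counts(config$n_studies, gp)
    st_counts <- pmax(st_counts, 1L)
    meta <- NULL
    study_offset <- 0L
    for (pi in seq_along(PARTITIONS)) {
      part <- PARTITIONS[pi]
      abbrev <- c(development = "dev", abiotic = "abio",
                  biotic = "bio", hormone = "horm")[part]
      for (g in seq_len(gp[pi])) {
        study <- sprintf("study%02d",
                         study_offset + ((g - 1L) %% st_counts[pi]) + 1L)
        grp <- sprintf("%s_g%d", abbrev, g)
        nrep <- sample(seq.int(config$replicates_range[1L],
                               config$replicates_range[2L]), 1L)
        meta <- rbind(meta, data.frame(
          sample_id = sprintf("%s_r%d", grp, seq_len(nrep)),
          study_id = study, replicate_group = grp, partition = part,
          stringsAsFactors = FALSE))
      }
      study_offset <- study_offset + st_counts[pi]
    }
    groups <- unique(meta$replicate_group)
    group_part <- stats::setNames(
      meta$partition[!duplicated(meta$replicate_group)], groups)
    studies <- unique(meta$study_id)
    batch <- stats::setNames(stats::rnorm(length(studies), 0,
                                          config$batch_sd_log2), studies)

    # gene classes and per-group expected log2 expression
    n <- config$n_genes
    counts <- allocate_counts(n, config$class_fractions[
      c("stable", "responsive", "tissue_absent", "housekeeping_like")])
    classes <- rep(c("stable", "responsive", "tissue_absent",
                     "housekeeping_like"), counts)
    genes <- sprintf("gene%04d", seq_len(n))
    names(classes) <- genes
    base <- stats::runif(n, config$base_log2_mean_range[1L],
                         config$base_log2_mean_range[2L])
    ng <- length(groups)
    expected <- matrix(rep(base, ng), n, ng,
                       dimnames = list(genes, groups))
    expressed <- matrix(TRUE, n, ng, dimnames = list(genes, groups))
    for (gi in seq_len(n)) {
      cls <- classes[gi]
      if (cls == "responsive") {
        hit <- stats::runif(ng) < config$response_prob
        sign <- ifelse(stats::runif(ng) < 0.5, -1, 1)
        expected[gi, hit] <- expected[gi, hit] +
          sign[hit] * config$responsive_effect_log2
      } else if (cls == "housekeeping_like") {
        expected[gi, ] <- expected[gi, ] +
          stats::rnorm(ng, 0, config$hk_wobble_sd_log2)
      } else if (cls == "tissue_absent") {
        n_absent <- sample(1:3, 1L)
        absent <- sample(ng, n_absent)
        expected[gi, absent] <- config$absent_log2
        expressed[gi, absent] <- FALSE
      }
    }

    # sample-level linear intensities
    smap <- match(meta$replicate_group, groups)
    eps <- matrix(stats::rnorm(n * nrow(meta), 0,
                               config$stable_noise_sd_log2),
                  n, nrow(meta))
    expr <- 2 ^ (expected[, smap, drop = FALSE] +
                 rep(batch[meta$study_id], each = n) + eps)
    dimnames(expr) <- list(genes, meta$sample_id)

    # probe-level PM/MM with fixed per-probe affinities
    np <- config$probe_pairs
    aff <- 2 ^ matrix(stats::rnorm(n * np, 0,
                                   config$probe_affinity_sd_log2), n, np)
    ns <- nrow(meta)
    pm_noise <- 2 ^ stats::rnorm(n * np * ns, 0, config$probe_noise_sd_log2)
    mm_noise <- 2 ^ stats::rnorm(n * np * ns, 0, config$probe_noise_sd_log2)
    # layout: gene fastest, then probe, then sample
    gene_idx <- rep(seq_len(n), times = np * ns)
    probe_idx <- rep(rep(seq_len(np), each = n), times = ns)
    sample_idx <- rep(seq_len(ns), each = n * np)
    signal <- expr[cbind(gene_idx, sample_idx)] * aff[cbind(gene_idx, probe_idx)]
    probes <- data.frame(
      probeset_id = genes[gene_idx],
      probe_index = probe_idx,
      pm = (config$background + signal) * pm_noise,
      mm = config$background * mm_noise,
      sample_id = meta$sample_id[sample_idx],
      stringsAsFactors = FALSE)

    structure(list(expr = expr, probes = probes, metadata = meta,
                   truth = list(class = classes,
                                expected_log2 = expected,
                                expressed = expressed),
                   config = config),
              class = "sim_compendium")
  })
}

#' @export
print.sim_compendium <- function(x, ...) {
  cat("Synthetic compendium: ", nrow(x$expr), " genes x ", ncol(x$expr),
      " samples (", length(unique(x$metadata$study_id)), " studies, ",
      length(unique(x$metadata$replicate_group)),
      " replicate groups)\n", sep = "")
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate a qPCR Ct table from ground truth
#'
#' Ct = offset - log2(expected expression) + Gaussian noise, one column
#' per selected replicate group (one pooled cDNA sample per group). At
#' zero noise, doubling the expected expression lowers Ct by exactly 1.
#'
#' @param truth Ground-truth list from [simulate_compendium()].
#' @param genes Gene ids to assay (default: all).
#' @param groups Replicate groups to assay (default: all).
#' @param noise_sd_ct SD of the Ct noise in cycles (default 0.15).
#' @param offset Ct of a transcript at log2 expression 0 (default 38).
#' @param gene_noise_mult Optional named multiplier on the noise SD for
#'   specific genes (e.g. to plant an unstable candidate).
#' @param seed RNG seed.
#' @return Numeric Ct matrix, genes x groups.
#' @export
simulate_ct <- function(truth, genes = NULL, groups = NULL,
                        noise_sd_ct = 0.15, offset = 38,
                        gene_noise_mult = NULL, seed = 1L) {
  genes <- genes %||% rownames(truth$expected_log2)
  groups <- groups %||% colnames(truth$expected_log2)
  stopifnot(all(genes %in% rownames(truth$expected_log2)),
            all(groups %in% colnames(truth$expected_log2)),
            noise_sd_ct >= 0)
  mult <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(gene_noise_mult))
    mult[names(gene_noise_mult)] <- gene_noise_mult
  with_seed(seed, {
    exp_l2 <- truth$expected_log2[genes, groups, drop = FALSE]
    noise <- matrix(stats::rnorm(length(exp_l2)), nrow(exp_l2)) *
      (noise_sd_ct * mult[genes])
    ct <- offset - exp_l2 + noise
    dimnames(ct) <- list(genes, groups)
    ct
  })
}
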