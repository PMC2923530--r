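# Partitioned mean/SD/CV stability statistics and candidate selection.
#
# CV = SD/mean is computed on linear-scale normalized intensities (sample
# SD, n-1 denominator) over three sample scopes: the developmental set,
# the stress set (abiotic + biotic) and the entire set (which also
# includes the hormone experiments). A gene is "stable" when its CV falls
# below the configured cut-off in one or more scopes; candidate reference
# genes are the lowest-CV genes per scope plus a seeded random draw from
# the remaining low-CV pool.

SCOPES <- c("development", "stress", "entire")

scope_samples <- function(metadata, scope) {
  scope <- match.arg(scope, SCOPES)
  keep <- switch(scope,
                 development = metadata$partition == "development",
                 stress = metadata$partition %in% c("abiotic", "biotic"),
                 entire = rep(TRUE, nrow(metadata)))
  metadata$sample_id[keep]
}

#' Per-gene mean, SD and CV over one sample scope
#'
#' @param expr Numeric expression matrix (genes x samples), linear scale.
#' @param metadata Metadata data.frame covering the matrix columns.
#' @param scope One of `"development"` (development partition), `"stress"`
#'   (abiotic + biotic partitions) or `"entire"` (all samples, hormone
#'   included).
#' @return A data.frame with columns `gene_id`, `partition` (the scope),
#'   `mean`, `sd`, `cv`. Genes with mean 0 get `cv = NA` (flagged,
#'   excluded from selection).
#' @export
partition_stats <- function(expr, metadata, scope = SCOPES) {
  scope <- match.arg(scope)
  expr <- validate_expression_matrix(expr, metadata)
  samples <- intersect(colnames(expr), scope_samples(metadata, scope))
  if (length(samples) == 0L)
    stop_("scope '", scope, "' selects no samples")
  sub <- expr[, samples, drop = FALSE]
  m <- rowMeans(sub)
  s <- apply(sub, 1L, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  out <- data.frame(gene_id = rownames(expr), partition = scope,
                    mean = m, sd = s, cv = cv,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Stability table over all three scopes
#'
#' Stacks [partition_stats()] rows for the developmental, stress and
#' entire scopes — the computed analogue of a published reference-gene
#' mean/SD/CV table.
#'
#' @inheritParams partition_stats
#' @param scopes Scopes to include (default all three).
#' @return A `stability_table` data.frame.
#' @export
stability_table <- function(expr, metadata, scopes = SCOPES) {
  out <- do.call(rbind, lapply(scopes, function(sc)
    partition_stats(expr, metadata, sc)))
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Rank genes by ascending CV within one scope
#'
#' @param stats A `stability_table` (possibly multi-scope).
#' @param scope Scope to rank within.
#' @return Character vector of gene ids, ascending CV, ties broken by
#'   lexicographic gene id; genes with undefined CV are omitted.
#' @export
rank_by_cv <- function(stats, scope = SCOPES) {
  scope <- match.arg(scope)
  rows <- stats[stats$partition == scope & !is.na(stats$cv), , drop = FALSE]
  if (nrow(rows) == 0L) stop_("no rows with defined CV for scope ", scope)
  rows$gene_id[order(rows$cv, rows$gene_id)]
}

#' Selection configuration
#'
#' Tunables of the candidate-selection step: how many lowest-CV genes to
#' take per scope, the per-scope CV cut-offs defining the stable set and
#' the size of the seeded random draw from the low-CV pool.
#'
#' @param top_k_stress,top_k_development,top_k_entire Number of lowest-CV
#'   picks per scope (defaults 2/2/3).
#' @param cv_cutoff_development,cv_cutoff_stress,cv_cutoff_entire CV
#'   cut-offs per scope; 0.35 — the conventional published value for the
#'   entire scope — is the default for every scope.
#' @param n_random_extra Number of extra genes drawn at random (without
#'   replacement, seeded) from stable genes with entire-scope CV at or
#'   below `cv_cutoff_entire` not already chosen (default 4).
#' @param rng_seed Seed for the random draw.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(top_k_stress = 2L, top_k_development = 2L,
                             top_k_entire = 3L,
                             cv_cutoff_development = 0.35,
                             cv_cutoff_stress = 0.35,
                             cv_cutoff_entire = 0.35,
                             n_random_extra = 4L, rng_seed = 1L) {
  stopifnot(top_k_stress >= 0, top_k_development >= 0, top_k_entire >= 0,
            n_random_extra >= 0, cv_cutoff_development > 0,
            cv_cutoff_stress > 0, cv_cutoff_entire > 0)
  structure(list(top_k_stress = as.integer(top_k_stress),
                 top_k_development = as.integer(top_k_development),
                 top_k_entire = as.integer(top_k_entire),
                 cv_cutoff_development = cv_cutoff_development,
                 cv_cutoff_stress = cv_cutoff_stress,
                 cv_cutoff_entire = cv_cutoff_entire,
                 n_random_extra = as.integer(n_random_extra),
                 rng_seed = rng_seed),
            class = "selection_config")
}

#' Stable-gene screen and reference-gene selection
#'
#' Applies the CV screen to the expressed-everywhere universe: a gene is
#' stable when its CV is below the scope cut-off in the developmental,
#' stress and/or entire scope (or-combination). Candidate reference genes
#' are then chosen sequentially — the lowest-CV stable genes in the stress
#' scope, then the developmental scope, then the entire scope (ties by
#' gene id, genes never chosen twice) — plus a seeded random draw from the
#' remaining stable genes with entire-scope CV at or below the entire
#' cut-off.
#'
#' @param stats A `stability_table` covering all three scopes.
#' @param universe Character vector of gene ids that passed the
#'   expressed-everywhere filter.
#' @param config A [selection_config()].
#' @return An object of class `ref_selection`: list with `stable_set`
#'   (character), `chosen` (data.frame `gene_id`, `provenance`, `cv`),
#'   `config` and `universe_size`. Warns if the stable pool cannot supply
#'   all requested picks.
#' @export
select_stable <- function(stats, universe, config = selection_config()) {
  cv_of <- function(scope) {
    rows <- stats[stats$partition == scope, , drop = FALSE]
    stats::setNames(rows$cv, rows$gene_id)[universe]
  }
  cv_dev <- cv_of("development")
  cv_str <- cv_of("stress")
  cv_ent <- cv_of("entire")
  if (anyNA(names(cv_ent)))
    stop_("stability table does not cover the whole universe")
  stable <- (!is.na(cv_dev) & cv_dev < config$cv_cutoff_development) |
            (!is.na(cv_str) & cv_str < config$cv_cutoff_stress) |
            (!is.na(cv_ent) & cv_ent < config$cv_cutoff_entire)
  stable_set <- universe[stable]

  chosen <- character(0)
  prov <- character(0)
  cvs <- numeric(0)
  take <- function(cv_vec, k, tag) {
    pool <- cv_vec[stable_set[!stable_set %in% chosen]]
    pool <- pool[!is.na(pool)]
    pool <- pool[order(pool, names(pool))]
    picks <- utils::head(names(pool), k)
    chosen <<- c(chosen, picks)
    prov <<- c(prov, rep(tag, length(picks)))
    cvs <<- c(cvs, unname(pool[picks]))
    if (length(picks) < k)
      warning("stable pool exhausted: only ", length(picks), " of ", k,
              " picks available for ", tag, call. = FALSE)
  }
  take(cv_str, config$top_k_stress, "lowest-CV-stress")
  take(cv_dev, config$top_k_development, "lowest-CV-development")
  take(cv_ent, config$top_k_entire, "lowest-CV-entire")

  pool <- stable_set[!stable_set %in% chosen]
  pool <- pool[!is.na(cv_ent[pool]) & cv_ent[pool] <= config$cv_cutoff_entire]
  k <- min(config$n_random_extra, length(pool))
  if (k < config$n_random_extra)
    warning("low-CV pool exhausted: only ", k, " of ",
            config$n_random_extra, " random picks available",
            call. = FALSE)
  extra <- with_seed(config$rng_seed, sample(pool, k))
  chosen <- c(chosen, extra)
  prov <- c(prov, rep("random-below-cutoff", length(extra)))
  cvs <- c(cvs, unname(cv_ent[extra]))

  structure(list(stable_set = stable_set,
                 chosen = data.frame(gene_id = chosen, provenance = prov,
                                     cv = cvs, stringsAsFactors = FALSE),
                 config = config, universe_size = length(universe)),
            class = "ref_selection")
}

#' @export
print.ref_selection <- function(x, ...) {
  cat("Reference-gene selection\n")
  cat("  universe (expressed everywhere):", x$universe_size, "genes\n")
  cat("  stable set (CV screen):", length(x$stable_set), "genes\n")
  cat("  chosen candidates:", nrow(x$chosen), "\n")
  invisible(x)
}

#' @export
summary.ref_selection <- function(object, ...) {
  print(object)
  if (nrow(object$chosen)) {
    cat("\n")
    print(object$chosen, row.names = FALSE)
  }
  invisible(object)
}
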