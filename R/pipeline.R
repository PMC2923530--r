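# End-to-end composition of the pipeline stages on a synthetic
# compendium: simulate -> detect -> filter -> stability -> select ->
# qPCR simulation -> geNORM -> combined report (+ clustering of the
# stable set).

#' Run the full reference-gene pipeline on a synthetic compendium
#'
#' Convenience driver used by the examples, the acceptance script and the
#' end-to-end tests. All randomness is derived from `seed`, so two runs
#' with the same seed produce byte-identical outputs.
#'
#' @param seed Master seed; the simulation uses it directly and the qPCR
#'   stage uses `seed + 1`.
#' @param config A [simulation_config()] (its own seed is overridden by
#'   `seed`).
#' @param detection A [detection_params()] list.
#' @param selection A [selection_config()] (its `rng_seed` is overridden
#'   by `seed`).
#' @param out_dir Optional directory; when given, the main tables are
#'   written there as TSV (expr.tsv, meta.tsv, calls.tsv, pvals.tsv,
#'   universe.txt, stability.tsv, selection.tsv, ct.tsv, genorm.tsv,
#'   report.tsv, cluster_order.txt).
#' @return A list with components `sim`, `calls`, `universe`,
#'   `stability`, `selection`, `ct`, `genorm`, `report`, `cluster`.
#' @export
run_pipeline <- function(seed = 42L, config = simulation_config(seed = seed),
                         detection = detection_params(),
                         selection = selection_config(rng_seed = seed),
                         out_dir = NULL) {
  config$seed <- seed
  selection$rng_seed <- seed
  sim <- simulate_compendium(config)
  calls <- detection_calls(sim$probes, detection)
  universe <- expressed_everywhere(calls, sim$metadata,
                                   alpha = detection$alpha_filter)
  stab <- stability_table(sim$expr, sim$metadata)
  sel <- select_stable(stab, universe, selection)
  ct <- simulate_ct(sim$truth, genes = sel$chosen$gene_id,
                    seed = seed + 1L)
  gn <- genorm(ct_to_relative_quantity(ct))
  report <- combined_report(gn, stab)
  cl <- if (length(sel$stable_set) >= 2L)
    hierarchical_cluster(
      average_replicates_log2(sim$expr, sim$metadata)[sel$stable_set, ,
                                                      drop = FALSE])
  else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_expression_matrix(sim$expr, p("expr.tsv"))
    write_sample_metadata(sim$metadata, p("meta.tsv"))
    write_call_set(calls, p("calls.tsv"), p("pvals.tsv"))
    writeLines(universe, p("universe.txt"))
    write_stability_table(stab, p("stability.tsv"))
    utils::write.table(sel$chosen, p("selection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_ct_table(ct, p("ct.tsv"))
    utils::write.table(
      data.frame(gene_id = gn$ranking$gene_id,
                 m_at_removal = fmt_full(gn$ranking$m_at_removal),
                 step = gn$ranking$step),
      p("genorm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    rep_out <- report
    rep_out$m <- fmt_full(rep_out$m)
    rep_out$cv <- fmt_full(rep_out$cv)
    utils::write.table(rep_out, p("report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    if (!is.null(cl)) writeLines(cl$leaf_order, p("cluster_order.txt"))
  }

  list(sim = sim, calls = calls, universe = universe, stability = stab,
       selection = sel, ct = ct, genorm = gn, report = report,
       cluster = cl)
}
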