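# geNORM-style stability engine, implemented from the published
# definition: for candidate genes j, k with relative quantities a_j, a_k
# across samples, the pairwise variation V_jk is the standard deviation
# (n-1) of log2(a_j/a_k); the stability measure M_j is the mean of V_jk
# over all other candidates. The least stable gene (highest M) is removed
# stepwise until two remain. Normalization factors are per-sample
# geometric means of the most stable genes, and the pairwise variation
# series V_{n/n+1} = SD(log2(NF_n/NF_{n+1})) decides how many reference
# genes are needed (conventionally V < 0.15).

#' Convert a Ct table to relative quantities
#'
#' Standard delta-Ct transform: per gene g and sample s,
#' a_gs = E_g^(minCt_g - Ct_gs), so the sample with the lowest Ct (most
#' template) maps to 1 and all quantities lie in (0, 1]. Missing Ct values
#' propagate as `NA` ("not measured").
#'
#' @param ct Numeric matrix (genes x samples) of cycle thresholds.
#' @param efficiency Amplification efficiency per gene: scalar or named
#'   vector (default 2, perfect doubling); must exceed 1.
#' @return Numeric matrix of relative quantities, same dimnames.
#' @export
ct_to_relative_quantity <- function(ct, efficiency = 2) {
  stopifnot(is.matrix(ct))
  if (length(efficiency) == 1L)
    efficiency <- stats::setNames(rep(efficiency, nrow(ct)), rownames(ct))
  eff <- efficiency[rownames(ct)]
  if (anyNA(eff) || any(eff <= 1))
    stop_("every gene needs an amplification efficiency > 1")
  measured <- rowSums(!is.na(ct))
  if (any(measured < 2L))
    stop_("gene(s) with fewer than 2 measured samples: ",
          paste(rownames(ct)[measured < 2L], collapse = ", "))
  mins <- apply(ct, 1L, min, na.rm = TRUE)
  eff ^ (mins - ct)
}

#' Pairwise variation between two genes
#'
#' V_jk = standard deviation (n-1 denominator) over samples of
#' log2(a_j/a_k), using pairwise-complete samples. Symmetric and
#' invariant to per-sample rescaling of both genes.
#'
#' @param a_j,a_k Positive quantity vectors over the same samples (`NA` =
#'   not measured).
#' @return Nonnegative scalar.
#' @export
pairwise_variation <- function(a_j, a_k) {
  stopifnot(length(a_j) == length(a_k))
  ok <- !is.na(a_j) & !is.na(a_k)
  if (sum(ok) < 2L)
    stop_("fewer than 2 common samples between the two genes")
  if (any(a_j[ok] <= 0) || any(a_k[ok] <= 0))
    stop_("relative quantities must be strictly positive")
  stats::sd(log2(a_j[ok] / a_k[ok]))
}

# Full V matrix (genes x genes, NA diagonal); errors name offending pairs.
pairwise_variation_matrix <- function(mat) {
  g <- nrow(mat)
  v <- matrix(NA_real_, g, g, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(g - 1L)) {
    for (k in seq.int(j + 1L, g)) {
      v[j, k] <- v[k, j] <- tryCatch(
        pairwise_variation(mat[j, ], mat[k, ]),
        error = function(e) stop_("pair (", rownames(mat)[j], ", ",
                                  rownames(mat)[k], "): ",
                                  conditionMessage(e)))
    }
  }
  v
}

#' Stability measure M
#'
#' M_j = arithmetic mean of the pairwise variations V_jk over all other
#' candidate genes k; lower M indicates more stable expression.
#'
#' @param mat Relative-quantity matrix (>= 3 genes x >= 2 samples).
#' @param gene Optional single gene id; if omitted, M is returned for all
#'   genes.
#' @return Named numeric vector of M values (or a scalar for one gene).
#' @export
stability_M <- function(mat, gene = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3L)
  v <- pairwise_variation_matrix(mat)
  m <- rowMeans(v, na.rm = TRUE)
  if (is.null(gene)) m else unname(m[gene])
}

#' Per-sample normalization factor
#'
#' Geometric mean of the selected reference genes' relative quantities in
#' each sample.
#'
#' @param mat Relative-quantity matrix.
#' @param genes Character vector (>= 2) of reference gene ids.
#' @return Named positive numeric vector, one factor per sample.
#' @export
normalization_factor <- function(mat, genes) {
  stopifnot(length(genes) >= 2L, all(genes %in% rownames(mat)))
  sub <- mat[genes, , drop = FALSE]
  if (any(!is.na(sub) & sub <= 0))
    stop_("relative quantities must be strictly positive")
  exp(colMeans(log(sub)))
}

#' geNORM stability analysis
#'
#' Runs the full engine on a relative-quantity matrix: M values for the
#' complete candidate panel, the stepwise exclusion ranking (repeatedly
#' removing the gene with the highest M, ties broken by lexicographically
#' smallest gene id, until two genes remain and share their final M), the
#' pairwise variation series V_{n/n+1} along the stability ranking, and
#' the recommended number of reference genes — the smallest n >= 2 with
#' V_{n/n+1} below `v_threshold`, or G-1 flagged "threshold never met".
#'
#' @param mat Relative-quantity matrix (>= 3 genes), e.g. from
#'   [ct_to_relative_quantity()].
#' @param v_threshold Pairwise-variation threshold (default 0.15, the
#'   conventional value).
#' @return An object of class `genorm`: list with
#'   \describe{
#'     \item{m_values}{named M vector for the full panel;}
#'     \item{ranking}{data.frame `gene_id`, `m_at_removal`, `step` from
#'       least to most stable (the final pair shares step and M);}
#'     \item{stability_order}{gene ids from most to least stable;}
#'     \item{v_series}{named vector V_{2/3} .. V_{(G-1)/G};}
#'     \item{recommended_n}{smallest n with V below threshold;}
#'     \item{threshold_met}{logical;}
#'     \item{v_threshold}{the threshold used.}
#'   }
#' @examples
#' ct <- rbind(g1 = c(20, 21, 23), g2 = c(25, 26, 28), g3 = c(18, 19, 21))
#' colnames(ct) <- paste0("s", 1:3)
#' fit <- genorm(ct_to_relative_quantity(ct))
#' fit$m_values  # all zero: the three genes are exactly proportional
#' @export
genorm <- function(mat, v_threshold = 0.15) {
  stopifnot(is.matrix(mat), v_threshold > 0)
  g <- nrow(mat)
  if (g < 3L) stop_("geNORM needs at least 3 candidate genes")
  if (ncol(mat) < 2L) stop_("geNORM needs at least 2 samples")

  v <- pairwise_variation_matrix(mat)
  m_full <- rowMeans(v, na.rm = TRUE)

  remaining <- rownames(mat)
  ranking <- data.frame(gene_id = character(0), m_at_removal = numeric(0),
                        step = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining) > 2L) {
    step <- step + 1L
    m <- rowMeans(v[remaining, remaining], na.rm = TRUE)
    worst <- sort(names(m)[m == max(m)])[1L]
    ranking <- rbind(ranking,
                     data.frame(gene_id = worst, m_at_removal = unname(m[worst]),
                                step = step, stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, worst)
  }
  final_m <- v[remaining[1L], remaining[2L]]
  step <- step + 1L
  ranking <- rbind(ranking,
                   data.frame(gene_id = sort(remaining),
                              m_at_removal = final_m, step = step,
                              stringsAsFactors = FALSE))
  stability_order <- rev(ranking$gene_id)

  v_series <- numeric(0)
  if (g >= 3L) {
    ns <- seq.int(2L, g - 1L)
    v_series <- vapply(ns, function(n) {
      nf_n <- normalization_factor(mat, stability_order[seq_len(n)])
      nf_n1 <- normalization_factor(mat, stability_order[seq_len(n + 1L)])
      ratio <- log2(nf_n / nf_n1)
      stats::sd(ratio[is.finite(ratio)])
    }, numeric(1))
    names(v_series) <- sprintf("V%d/%d", ns, ns + 1L)
  }
  met <- which(v_series < v_threshold)
  threshold_met <- length(met) > 0L
  recommended_n <- if (threshold_met) as.integer(met[1L] + 1L) else g - 1L

  structure(list(m_values = m_full, ranking = ranking,
                 stability_order = stability_order, v_series = v_series,
                 recommended_n = recommended_n,
                 threshold_met = threshold_met,
                 v_threshold = v_threshold,
                 n_genes = g, n_samples = ncol(mat)),
            class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNORM stability analysis: ", x$n_genes, " genes x ",
      x$n_samples, " samples\n", sep = "")
  cat("  most stable:",
      paste(utils::head(x$stability_order, 3L), collapse = ", "), "\n")
  cat("  recommended number of reference genes:", x$recommended_n,
      if (!x$threshold_met) "(threshold never met)" else "", "\n")
  invisible(x)
}

#' @export
summary.genorm <- function(object, ...) {
  print(object)
  cat("\nStepwise exclusion (least stable first):\n")
  print(object$ranking, row.names = FALSE)
  cat("\nPairwise variation series (threshold ",
      object$v_threshold, "):\n", sep = "")
  print(round(object$v_series, 4))
  invisible(object)
}

#' @export
coef.genorm <- function(object, ...) object$m_values

#' Plot a geNORM analysis
#'
#' Two base-graphics panels: average expression stability M at each
#' exclusion step (least stable on the left, following the usual geNORM
#' output) and the pairwise variation series with the decision threshold.
#'
#' @param x A `genorm` object.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.genorm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  r <- x$ranking
  graphics::plot(r$step, r$m_at_removal, type = "b", pch = 19,
                 xaxt = "n", xlab = "", ylab = "average stability M",
                 main = "Stepwise exclusion")
  graphics::axis(1, at = r$step, labels = r$gene_id, las = 2,
                 cex.axis = 0.7)
  graphics::barplot(x$v_series, las = 2, ylab = "pairwise variation V",
                    main = "How many reference genes?")
  graphics::abline(h = x$v_threshold, lty = 2)
  invisible(x)
}
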