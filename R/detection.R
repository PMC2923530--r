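# Present/absent detection calls from PM/MM probe pairs.
#
# A probe pair's discrimination score R = (PM - MM)/(PM + MM) lies in
# (-1, 1): near 0 for background, approaching 1 for strong signal. A
# probeset is tested for presence with a one-sided Wilcoxon signed-rank
# test of H0: median(R) = tau against H1: median(R) > tau. The exact null
# (all 2^n sign assignments equally likely) is used for up to 25
# informative pairs — Affymetrix probesets carry 11, so the exact path is
# the operative one — with a continuity-corrected normal approximation
# beyond that.

#' Detection-call parameters
#'
#' @param tau Small positive offset subtracted from the discrimination
#'   scores before the signed-rank test; the default 0.015 is the
#'   conventional MAS-style value.
#' @param alpha_present p-value threshold below which a probeset is called
#'   Present (default 0.04).
#' @param alpha_marginal p-value threshold below which a probeset is called
#'   Marginal (default 0.06); at or above it the call is Absent.
#' @param alpha_filter p-value threshold used by the compendium-wide
#'   expressed-everywhere filter (default 0.05); kept separate from the
#'   call thresholds because the filter criterion is stated directly on
#'   the detection p-value.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(tau = 0.015, alpha_present = 0.04,
                             alpha_marginal = 0.06, alpha_filter = 0.05) {
  stopifnot(tau >= 0, alpha_present > 0,
            alpha_present <= alpha_marginal, alpha_marginal < 0.5,
            alpha_filter > 0, alpha_filter < 1)
  structure(list(tau = tau, alpha_present = alpha_present,
                 alpha_marginal = alpha_marginal,
                 alpha_filter = alpha_filter),
            class = "detection_params")
}

#' Discrimination scores for one probeset in one sample
#'
#' R_i = (PM_i - MM_i)/(PM_i + MM_i) per probe pair, in probe order.
#' Pairs with PM + MM = 0 carry no information and are returned as `NA`
#' (excluded downstream).
#'
#' @param pm,mm Numeric vectors of perfect-match and mismatch intensities.
#' @return Numeric vector of scores in (-1, 1), `NA` for uninformative
#'   pairs.
#' @export
discrimination_scores <- function(pm, mm) {
  stopifnot(length(pm) == length(mm), length(pm) >= 1L)
  tot <- pm + mm
  r <- (pm - mm) / tot
  r[tot == 0] <- NA_real_
  r
}

#' One-sided signed-rank detection p-value
#'
#' Tests H0: median(R) = tau against H1: median(R) > tau. Scores equal to
#' tau are dropped before ranking (zero-difference ties); rank ties get
#' midranks. With n <= 25 informative scores the exact null distribution
#' of the positive-rank sum is computed by dynamic programming over the
#' 2^n equally likely sign assignments; above that a normal approximation
#' with continuity correction is used.
#'
#' @param scores Numeric vector of discrimination scores (`NA` =
#'   uninformative pair, dropped).
#' @param tau Null median (default 0.015).
#' @return p-value in (0, 1], or `NA_real_` if fewer than 3 informative
#'   scores remain (indeterminate; treated as Absent by the filter).
#' @export
detection_pvalue <- function(scores, tau = 0.015) {
  d <- scores[!is.na(scores)] - tau
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L) return(NA_real_)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= 25L) {
    # Exact distribution of W = sum of a uniformly random subset of the
    # (possibly midrank, hence half-integer) ranks. Doubling makes ranks
    # integral; f[s+1] counts sign assignments with doubled sum s.
    r2 <- as.integer(round(2 * rk))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (r in r2) {
      idx <- seq.int(total + 1L, r + 1L)
      f[idx] <- f[idx] + f[idx - r]
    }
    w2 <- as.integer(round(2 * w))
    p <- sum(f[seq.int(w2 + 1L, total + 1L)]) / 2^n
  } else {
    mu <- sum(rk) / 2
    sigma <- sqrt(sum(rk^2) / 4)
    p <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Convert a detection p-value to a P/M/A call
#'
#' Present if p < `alpha_present`, Marginal if `alpha_present` <= p <
#' `alpha_marginal`, Absent otherwise (including indeterminate `NA`
#' p-values).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param params A [detection_params()] list.
#' @return Character vector of calls `"P"`, `"M"` or `"A"`.
#' @export
call_from_p <- function(p, params = detection_params()) {
  out <- ifelse(is.na(p), "A",
                ifelse(p < params$alpha_present, "P",
                       ifelse(p < params$alpha_marginal, "M", "A")))
  as.character(out)
}

#' Detection calls for a probe-level table
#'
#' Computes discrimination scores and signed-rank detection p-values for
#' every (probeset, sample) cell of a long-format probe table, and the
#' corresponding P/M/A calls.
#'
#' @param probes Probe-level data.frame (see [read_probe_table()]).
#' @param params A [detection_params()] list.
#' @return An object of class `call_set`: list with `calls` (character
#'   matrix genes x samples), `p_value` (numeric matrix) and `params`.
#'   Row order follows first appearance of each probeset, column order
#'   first appearance of each sample.
#' @export
detection_calls <- function(probes, params = detection_params()) {
  probes <- validate_probe_table(probes)
  genes <- unique(probes$probeset_id)
  samples <- unique(probes$sample_id)
  r <- discrimination_scores(probes$pm, probes$mm)
  gi <- match(probes$probeset_id, genes)
  si <- match(probes$sample_id, samples)
  cell <- (si - 1L) * length(genes) + gi
  ord <- order(cell, probes$probe_index)
  groups <- split(r[ord], cell[ord])
  p <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  p[as.integer(names(groups))] <-
    vapply(groups, detection_pvalue, numeric(1), tau = params$tau)
  calls <- matrix(call_from_p(p, params), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  structure(list(calls = calls, p_value = p, params = params),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c("P", "M", "A")))
  cat("Detection call set: ", nrow(x$calls), " probesets x ",
      ncol(x$calls), " samples\n", sep = "")
  cat(sprintf("  P: %d  M: %d  A: %d\n", tab["P"], tab["M"], tab["A"]))
  invisible(x)
}

#' Compendium-wide expressed-everywhere filter
#'
#' Returns the genes whose detection p-value is below `alpha` in every
#' sample of every replicate group — i.e. transcripts reliably detected in
#' all replicates of all biological samples, the first gate of the
#' reference-gene selection scheme. Indeterminate (`NA`) p-values count as
#' not detected.
#'
#' @param calls A `call_set` from [detection_calls()], or a numeric
#'   p-value matrix (genes x samples).
#' @param metadata Optional metadata; when supplied, every sample column
#'   must have a metadata row.
#' @param alpha Detection p-value threshold (default 0.05).
#' @return Character vector of gene ids, in the input row order.
#' @export
expressed_everywhere <- function(calls, metadata = NULL, alpha = 0.05) {
  p <- if (inherits(calls, "call_set")) calls$p_value else calls
  stopifnot(is.matrix(p))
  if (nrow(p) == 0L || ncol(p) == 0L) return(character(0))
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    unknown <- setdiff(colnames(p), metadata$sample_id)
    if (length(unknown))
      stop_("sample column(s) absent from metadata: ",
            paste(unknown, collapse = ", "))
  }
  ok <- !is.na(p) & p < alpha
  rownames(p)[rowSums(ok) == ncol(p)]
}
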