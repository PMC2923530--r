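# Replicate-averaged log2 matrices, average-linkage hierarchical
# clustering and the combined M + CV report.

#' Replicate-averaged log2 expression
#'
#' Averages log2 intensities within each biological replicate group:
#' value = mean over replicates of log2(max(intensity, floor)). Columns
#' follow the order in which replicate groups first appear in the
#' metadata.
#'
#' @param expr Linear-scale expression matrix (genes x samples).
#' @param metadata Metadata data.frame; every sample column must map to a
#'   replicate group.
#' @param floor Lower clamp applied before taking log2 (default 1, so
#'   sub-unit normalized intensities do not produce unbounded negative
#'   logs).
#' @return Numeric matrix, genes x replicate groups.
#' @export
average_replicates_log2 <- function(expr, metadata, floor = 1) {
  expr <- validate_expression_matrix(expr, metadata)
  stopifnot(floor > 0)
  grp <- stats::setNames(metadata$replicate_group, metadata$sample_id)
  groups <- unique(metadata$replicate_group[
    metadata$sample_id %in% colnames(expr)])
  lg <- log2(pmax(expr, floor))
  out <- vapply(groups, function(g) {
    cols <- colnames(expr)[grp[colnames(expr)] == g]
    if (length(cols) == 0L) stop_("replicate group with zero samples: ", g)
    rowMeans(lg[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), groups)
  out
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA-style agglomerative clustering of the matrix rows on Euclidean
#' distance: at each step the pair of clusters with the smallest average
#' pairwise distance is merged (Lance-Williams update); ties in the
#' minimal distance are broken by the smallest (i, j) index pair in
#' cluster-creation order, making the result deterministic for a given
#' row order. Average linkage is reducible, so merge heights are
#' nondecreasing.
#'
#' @param mat Numeric matrix with >= 2 rows and finite values.
#' @return An object of classes `c("refstab_hclust", "hclust")` with the
#'   usual `merge`, `height`, `order` and `labels` components, so
#'   `plot()`, `cutree()` and `stats::cophenetic()` apply; plus
#'   `leaf_order`, the labels in dendrogram order.
#' @export
hierarchical_cluster <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (any(!is.finite(mat))) stop_("non-finite values in clustering input")
  n <- nrow(mat)
  labels <- rownames(mat) %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(mat))
  diag(d) <- Inf

  size <- rep(1L, n)                 # active cluster sizes
  id <- -seq_len(n)                  # hclust coding: negative = leaf
  active <- seq_len(n)               # columns of d still in play
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- active[best[1L, 1L]]
    j <- active[best[1L, 2L]]
    height[step] <- d[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    # Lance-Williams average-linkage update, merged cluster kept in slot i
    others <- setdiff(active, c(i, j))
    d[i, others] <- d[others, i] <-
      (size[i] * d[i, others] + size[j] * d[j, others]) /
      (size[i] + size[j])
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
    d[j, ] <- d[, j] <- Inf
  }

  # leaf order by left-to-right traversal of the merge tree
  traverse <- function(node) {
    if (node < 0L) return(-node)
    c(traverse(merge[node, 1L]), traverse(merge[node, 2L]))
  }
  ord <- traverse(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, leaf_order = labels[ord],
                 method = "average", dist.method = "euclidean",
                 call = match.call()),
            class = c("refstab_hclust", "hclust"))
}

#' Two-group Student's t-test
#'
#' Two-sided t-test on replicate intensity vectors (equal-variance pooled
#' test by default, Welch by flag), with a significance flag at `alpha`.
#' The degenerate case of zero variance in both groups is handled
#' explicitly: equal means give p = 1, distinct means p = 0.
#'
#' @param values_a,values_b Numeric vectors, >= 2 values each.
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @param alpha Significance level for the flag (default 0.01).
#' @return List with `statistic`, `p_value`, `significant`.
#' @export
two_group_t_test <- function(values_a, values_b, var_equal = TRUE,
                             alpha = 0.01) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    res <- list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0)
  } else {
    fit <- stats::t.test(values_a, values_b, var.equal = var_equal)
    res <- list(statistic = unname(fit$statistic),
                p_value = fit$p.value)
  }
  res$significant <- res$p_value < alpha
  res
}

#' Combined M + CV stability report
#'
#' Joins geNORM M values with entire-scope CVs: the most stable genes are
#' those with both low M and low CV. Rows are sorted by M ascending, then
#' CV ascending, then gene id; genes present in only one input are kept,
#' flagged, and listed last (the analogue of marking genes not expressed
#' in all arrays with an asterisk).
#'
#' @param genorm_fit A `genorm` object (or a named numeric M vector).
#' @param stats A `stability_table` covering the `entire` scope.
#' @return A data.frame with columns `gene_id`, `m`, `cv`, `flag`.
#' @export
combined_report <- function(genorm_fit, stats) {
  m <- if (inherits(genorm_fit, "genorm")) genorm_fit$m_values
       else genorm_fit
  ent <- stats[stats$partition == "entire", , drop = FALSE]
  cv <- stats::setNames(ent$cv, ent$gene_id)
  genes <- union(names(m), names(cv))
  if (length(intersect(names(m), names(cv))) == 0L)
    stop_("no genes shared between the geNORM result and the stability table")
  out <- data.frame(gene_id = genes,
                    m = unname(m[genes]),
                    cv = unname(cv[genes]),
                    stringsAsFactors = FALSE)
  out$flag <- is.na(out$m) | is.na(out$cv)
  out <- out[order(out$flag, out$m, out$cv, out$gene_id,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
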