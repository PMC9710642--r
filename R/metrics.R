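#' Alpha diversity of one count vector
#'
#' Within-sample diversity of a single count (or abundance) vector:
#' Shannon entropy `-sum(p * log(p))` over nonzero proportions, the
#' Gini-Simpson index `1 - sum(p^2)`, or richness (number of nonzero
#' entries).
#'
#' @param counts_row Nonnegative vector with positive sum.
#' @param index One of `"shannon"` (default), `"simpson"`, `"richness"`.
#' @return A nonnegative scalar.
#' @examples
#' alpha_diversity(rep(5, 8))            # log(8)
#' alpha_diversity(c(5, 3, 2), "richness")
#' @export
alpha_diversity <- function(counts_row, index = c("shannon", "simpson", "richness")) {
  index <- match.arg(index)
  if (any(!is.finite(counts_row)) || any(counts_row < 0))
    glv_domain_error("`counts_row` must be finite and nonnegative")
  tot <- sum(counts_row)
  if (tot <= 0) glv_domain_error("`counts_row` must have a positive sum")
  p <- counts_row[counts_row > 0] / tot
  switch(index,
    shannon = -sum(p * log(p)),
    simpson = 1 - sum(p^2),
    richness = length(p))
}

#' Fraction of zero entries in a count matrix
#'
#' @param counts Nonempty numeric matrix.
#' @return Fraction of exactly-zero entries, in \[0, 1\].
#' @export
sparsity <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) glv_domain_error("`counts` must be nonempty")
  mean(counts == 0)
}

#' Per-feature differential abundance between two count datasets
#'
#' Converts both matrices to per-sample relative abundances, then reports
#' per feature the shift in mean relative abundance (dataset b minus
#' dataset a) and a Wilcoxon rank-sum p-value, Benjamini-Hochberg adjusted
#' across features. Intended for realism checks (simulated vs empirical or
#' simulated vs simulated); the test is deliberately simple and
#' replaceable.
#'
#' @param counts_a,counts_b Matrices with samples in rows and the same
#'   features in columns.
#' @return Data frame with columns `feature`, `shift`, `p_value`,
#'   `p_adjusted`, one row per feature.
#' @export
differential_abundance <- function(counts_a, counts_b) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) != ncol(counts_b))
    glv_domain_error(sprintf(
      "feature counts differ: %d vs %d", ncol(counts_a), ncol(counts_b)))
  rel_a <- to_relative(counts_a)
  rel_b <- to_relative(counts_b)
  p <- vapply(seq_len(ncol(rel_a)), function(f) {
    a <- rel_a[, f]; b <- rel_b[, f]
    if (max(c(a, b)) == min(c(a, b))) return(1)  # all tied: no evidence
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(
    feature = colnames(counts_a) %||% paste0("feature_", seq_len(ncol(counts_a))),
    shift = colMeans(rel_b) - colMeans(rel_a),
    p_value = p,
    p_adjusted = p.adjust(p, method = "BH"),
    row.names = NULL)
}

#' Realism comparison of two count datasets
#'
#' Bundles the three standard realism axes for judging whether a simulated
#' dataset resembles a reference: the distribution of per-sample alpha
#' diversities, overall sparsity, and per-feature differential abundance.
#'
#' @param counts_a,counts_b Count matrices, samples x features (same
#'   features).
#' @param index Alpha-diversity index, see [alpha_diversity()].
#' @return An object of class `realism_report`: list with `alpha_a`,
#'   `alpha_b` (per-sample diversities), `sparsity_a`, `sparsity_b` and
#'   `per_feature_stats` (the [differential_abundance()] table).
#' @export
realism_report <- function(counts_a, counts_b, index = "shannon") {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  structure(
    list(
      alpha_a = apply(counts_a, 1L, alpha_diversity, index = index),
      alpha_b = apply(counts_b, 1L, alpha_diversity, index = index),
      sparsity_a = sparsity(counts_a),
      sparsity_b = sparsity(counts_b),
      per_feature_stats = differential_abundance(counts_a, counts_b),
      index = index),
    class = "realism_report")
}

#' @export
print.realism_report <- function(x, ...) {
  cat(sprintf(
    "<realism_report> %s alpha: %.3f vs %.3f (medians); sparsity: %.3f vs %.3f; %d/%d features BH-significant at 0.05\n",
    x$index, stats::median(x$alpha_a), stats::median(x$alpha_b),
    x$sparsity_a, x$sparsity_b,
    sum(x$per_feature_stats$p_adjusted < 0.05), nrow(x$per_feature_stats)))
  invisible(x)
}

#' Extract a samples-by-features count matrix from a cohort
#'
#' Pulls the observed count rows feeding the realism metrics: by default
#' the final recorded time point of each individual (endpoint comparison),
#' or all time points pooled.
#'
#' @param timecourses A `timecourse` or list of them.
#' @param node Restrict to one node's columns; `NULL` keeps all.
#' @param timepoint `"final"` (default) or `"all"`.
#' @param matrix_name Which matrix to extract: `"Y"` (default, observed
#'   counts), `"X"` or `"Z"`.
#' @return Numeric matrix, one row per sample.
#' @export
cohort_counts <- function(timecourses, node = NULL,
                          timepoint = c("final", "all"), matrix_name = "Y") {
  timepoint <- match.arg(timepoint)
  if (inherits(timecourses, "timecourse")) timecourses <- list(timecourses)
  rows <- lapply(timecourses, function(tc) {
    m <- tc[[matrix_name]]
    if (!is.null(node)) {
      if (!node %in% tc$node_names) glv_config_error(sprintf("unknown node '%s'", node))
      m <- m[, grep(paste0("^", node, "_"), colnames(m)), drop = FALSE]
    }
    if (timepoint == "final") m[nrow(m), , drop = FALSE] else m
  })
  do.call(rbind, rows)
}
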