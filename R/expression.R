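#' Median-based expression fold change between mutated and wild-type samples
#'
#' `fc = median(expr | mutated) / median(expr | wild-type)`. A wild-type
#' median of zero leaves the ratio undefined; callers (the scan) skip and
#' log such records rather than fabricate a pseudocount.
#'
#' @param expr_mut,expr_wt Non-empty numeric vectors of expression (CPM).
#' @return The fold change, or `NA_real_` when the wild-type median is 0.
#' @export
fold_change <- function(expr_mut, expr_wt) {
  if (length(expr_mut) == 0L || length(expr_wt) == 0L)
    stop("both groups must be non-empty")
  m1 <- stats::median(expr_mut)
  m2 <- stats::median(expr_wt)
  if (!is.finite(m1) || !is.finite(m2)) stop("medians must be finite")
  if (m2 == 0) return(NA_real_)
  m1 / m2
}

#' Two-sided Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact null distribution when the combined size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param expr_mut,expr_wt Numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(expr_mut, expr_wt) {
  if (length(expr_mut) < 2L || length(expr_wt) < 2L)
    stop("each group needs at least 2 observations")
  ties <- anyDuplicated(c(expr_mut, expr_wt)) > 0L
  exact <- (length(expr_mut) + length(expr_wt) <= 20L) && !ties
  suppressWarnings(
    stats::wilcox.test(expr_mut, expr_wt, exact = exact,
                       correct = TRUE)$p.value)
}

#' Expression association scan over mutated units
#'
#' For every (gene, unit) pair with at least `min_mut` mutated samples,
#' compares the gene's expression between mutated and wild-type samples:
#' median fold change, two-sided rank-sum p, and a direction call
#' (`over` if fc > `fc_hi`, `under` if fc < `fc_lo`, else `neutral`).
#' The unit is an RE (RE-level matrix plus RE-gene associations) or the
#' gene's CREAG (gene-level matrix from [creag_indicator()], identity
#' pairs). Samples are the intersection of the expression and mutation
#' matrices' samples. Records skipped for a zero wild-type median are
#' listed in the `"skipped"` attribute.
#'
#' @param matrix A [build_mutation_matrix()] result (or CREAG-level
#'   equivalent).
#' @param expr [signal_matrix()] of gene expression.
#' @param pairs data.frame with `unit_id`, `gene_id` linking matrix rows
#'   to genes.
#' @param min_mut Minimum mutated-sample count (default 2).
#' @param fc_hi,fc_lo Over-/under-expression fold-change bounds
#'   (defaults 2 and 0.5).
#' @return data.frame (`gene_id`, `unit_id`, `n_mut`, `n_wt`, `fc`,
#'   `log2fc`, `p_ranksum`, `direction`).
#' @export
mutation_expression_scan <- function(matrix, expr, pairs, min_mut = 2,
                                     fc_hi = 2, fc_lo = 0.5) {
  shared <- intersect(colnames(expr), matrix$sample_ids)
  if (length(shared) == 0L)
    stop("alignment error: no samples shared by expression and mutations")
  message("expression scan over ", length(shared), " shared sample(s)")
  ind <- matrix$indicator[, match(shared, matrix$sample_ids), drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$unit_id[i]; g <- pairs$gene_id[i]
    if (!(u %in% matrix$re_ids) || !(g %in% rownames(expr))) next
    mut <- ind[match(u, matrix$re_ids), ] == 1L
    if (sum(mut) < min_mut || sum(!mut) < 2L) next
    e <- expr[g, shared]
    fc <- fold_change(e[mut], e[!mut])
    if (is.na(fc)) {
      skipped <- c(skipped, paste0(g, "/", u, ": wild-type median 0"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, unit_id = u, n_mut = sum(mut), n_wt = sum(!mut),
      fc = fc, log2fc = log2(fc),
      p_ranksum = ranksum_test(e[mut], e[!mut]),
      direction = if (fc > fc_hi) "over" else if (fc < fc_lo) "under"
                  else "neutral",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(gene_id = character(0), unit_id = character(0),
                    n_mut = integer(0), n_wt = integer(0), fc = numeric(0),
                    log2fc = numeric(0), p_ranksum = numeric(0),
                    direction = character(0))
  if (length(skipped))
    message(length(skipped), " record(s) skipped for zero wild-type median")
  attr(out, "skipped") <- skipped
  out
}

#' Collapse an RE-level mutation matrix to CREAG (gene) level
#'
#' A sample is mutated for a gene iff it carries an SNV in any member RE
#' of the gene's CREAG.
#'
#' @param matrix RE-level [build_mutation_matrix()] result.
#' @param creags CREAG table from [build_creags()].
#' @return A `mutation_matrix` with one row per gene.
#' @export
creag_indicator <- function(matrix, creags) {
  ind <- matrix(0L, nrow(creags), length(matrix$sample_ids),
                dimnames = list(creags$gene_id, matrix$sample_ids))
  cnt <- ind
  for (j in seq_len(nrow(creags))) {
    rows <- match(creags$re_ids[[j]], matrix$re_ids)
    if (anyNA(rows)) stop("CREAG member RE absent from mutation matrix")
    cnt[j, ] <- colSums(matrix$snv_count[rows, , drop = FALSE])
    ind[j, ] <- (colSums(matrix$indicator[rows, , drop = FALSE]) > 0) * 1L
  }
  out <- list(indicator = ind, snv_count = cnt, re_ids = rownames(ind),
              sample_ids = colnames(ind))
  class(out) <- "mutation_matrix"
  out
}

#' Two-sided sign (exact binomial) test of expression-direction skew
#'
#' Tests whether over- and under-expression calls are balanced: an exact
#' two-sided binomial test of `n_over` successes in `n_over + n_under`
#' trials at probability 0.5.
#'
#' @param n_over,n_under Counts of over- and under-expressed genes.
#' @return Two-sided p-value.
#' @export
skew_test <- function(n_over, n_under) {
  if (n_over + n_under < 1L) stop("need at least one directional call")
  stats::binom.test(n_over, n_over + n_under, p = 0.5)$p.value
}
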