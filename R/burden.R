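#' Covered regions: the union of H3K27ac-positive intervals
#'
#' The background-rate denominator. Overlapping input intervals are merged
#' so that the total coverage counts every base once.
#'
#' @param res A [regulatory_set()] of active regions.
#' @return A `covered_regions` object: list with `intervals` (disjoint
#'   [regulatory_set()]) and `n_cov` (total width in bp).
#' @export
covered_regions <- function(res) {
  red <- GenomicRanges::reduce(as_gr(res))
  iv <- regulatory_set(as.character(GenomicRanges::seqnames(red)),
                       GenomicRanges::start(red) - 1L,
                       GenomicRanges::end(red),
                       name_prefix = "COV")
  out <- list(intervals = iv, n_cov = sum(interval_width(iv)))
  class(out) <- "covered_regions"
  out
}

#' Per-sample background mutation rates
#'
#' The rate of sample k is the ratio of its filtered non-coding SNV count
#' to the total covered width: `p_k = n_k / n_cov`.
#'
#' @param counts data.frame with `sample_id` and `n_k`
#'   (see [sample_snv_counts()]).
#' @param covered A [covered_regions()] object (or a number, the covered
#'   width in bp).
#' @return data.frame with `sample_id`, `n_k`, `p_k`.
#' @export
background_rates <- function(counts, covered) {
  n_cov <- if (inherits(covered, "covered_regions")) covered$n_cov
           else as.numeric(covered)
  if (n_cov <= 0) stop("n_cov must be positive")
  if (any(counts$n_k >= n_cov))
    stop("sample SNV count >= covered width; rate would reach 1")
  data.frame(sample_id = counts$sample_id, n_k = counts$n_k,
             p_k = counts$n_k / n_cov, stringsAsFactors = FALSE)
}

#' Probability that a sample hits a region at least once
#'
#' `1 - (1 - p_k)^width`, evaluated stably via `expm1`/`log1p`.
#'
#' @param p_k Per-bp background probability (vectorized), in `[0, 1)`.
#' @param width Region width in bp (>= 1).
#' @return Hit probability.
#' @export
hit_probability <- function(p_k, width) {
  if (any(p_k < 0 | p_k >= 1)) stop("p_k must be in [0, 1)")
  if (any(width < 1)) stop("width must be >= 1")
  -expm1(width * log1p(-p_k))
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities, computed by the iterative
#' convolution dynamic program over trials (exact, O(n^2)).
#'
#' @param probs Numeric vector of success probabilities in `[0, 1)`.
#' @return Numeric vector of length `length(probs) + 1`: P(X = 0..n).
#' @export
pbd_pmf <- function(probs) {
  if (length(probs) < 1L) stop("need at least one probability")
  if (any(probs < 0 | probs >= 1)) stop("probabilities must be in [0, 1)")
  n <- length(probs)
  pmf <- c(1, numeric(n))
  for (k in seq_len(n)) {
    p <- probs[k]
    idx <- seq_len(k) + 1L
    pmf[idx] <- pmf[idx] * (1 - p) + pmf[idx - 1L] * p
    pmf[1L] <- pmf[1L] * (1 - p)
  }
  pmf
}

#' Poisson-binomial upper-tail probability P(X >= s)
#'
#' Summed from the largest count downward (smallest terms first) for
#' numerical stability; `s = 0` returns exactly 1.
#'
#' @param probs Success probabilities in `[0, 1)`.
#' @param s Observed count, `0 <= s <= length(probs)`.
#' @return The tail probability.
#' @export
pbd_tail <- function(probs, s) {
  n <- length(probs)
  if (s < 0 || s > n) stop("s out of range [0, ", n, "]")
  if (s == 0) return(1)
  pmf <- pbd_pmf(probs)
  sum(pmf[(n + 1L):(s + 1L)])
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: with ordered p-values p_(1) <= ... <= p_(m),
#' q_(i) = min over j >= i of p_(j) m / j, capped at 1, returned in the
#' input order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# internal: shared burden engine; widths and mutated-sample counts per unit
burden_core <- function(unit_id, s, n, rates, fdr) {
  ord_rates <- rates$p_k
  results <- data.frame(unit_id = unit_id, s = as.integer(s), n = n,
                        stringsAsFactors = FALSE)
  # group identical widths so the PBD is convolved once per distinct width
  uw <- unique(n)
  pv <- numeric(length(n))
  for (w in uw) {
    probs <- hit_probability(ord_rates, w)
    pmf <- pbd_pmf(probs)
    tails <- rev(cumsum(rev(pmf)))           # tails[k+1] = P(X >= k)
    idx <- which(n == w)
    pv[idx] <- ifelse(s[idx] == 0, 1, tails[s[idx] + 1L])
  }
  results$p_value <- pmin(pv, 1)
  results$q_value <- bh_adjust(results$p_value)
  results$fmre <- results$q_value <= fdr
  results <- results[order(results$p_value, results$unit_id), , drop = FALSE]
  rownames(results) <- NULL
  results
}

#' Poisson-binomial mutational burden per regulatory element
#'
#' For RE i of width n_i, the number of mutated samples X_i follows a
#' Poisson-binomial distribution with per-sample probabilities
#' `1 - (1 - p_k)^{n_i}`; the p-value is the upper tail P(X_i >= s_i) at
#' the observed mutated-sample count, BH-adjusted across REs. Elements
#' with `q <= fdr` are flagged as frequently mutated (FMREs).
#'
#' @param matrix A [build_mutation_matrix()] result.
#' @param rates Per-sample rates from [background_rates()]; defines the
#'   cohort (samples absent from the matrix count as unmutated).
#' @param res [regulatory_set()] supplying the widths n_i.
#' @param fdr FDR threshold for the FMRE flag (default 0.25).
#' @return data.frame (`unit_id`, `s`, `n`, `p_value`, `q_value`, `fmre`)
#'   sorted by p-value.
#' @export
re_burden <- function(matrix, rates, res, fdr = 0.25) {
  if (!all(matrix$sample_ids %in% rates$sample_id))
    stop("mutation matrix contains samples without background rates")
  widths <- interval_width(res)[match(matrix$re_ids, res$name)]
  if (anyNA(widths))
    stop("missing RE width for: ",
         paste(utils::head(matrix$re_ids[is.na(widths)], 3L), collapse = ", "))
  ind <- matrix$indicator[, match(rates$sample_id, matrix$sample_ids),
                          drop = FALSE]
  ind[is.na(ind)] <- 0L                     # cohort samples with no SNVs
  s <- as.integer(rowSums(ind))
  burden_core(matrix$re_ids, s, widths, rates, fdr)
}

#' Poisson-binomial mutational burden per CREAG (gene level)
#'
#' Member REs and any annotated promoter of gene j are combined into a
#' pseudo-RE of width n_j (the sum of member widths); s_j counts samples
#' with at least one SNV in ANY member RE.
#'
#' @param matrix A [build_mutation_matrix()] result covering the member REs.
#' @param rates Per-sample rates from [background_rates()].
#' @param creags CREAG table from [build_creags()] (columns `gene_id`,
#'   `re_ids` list-column, `n_j`).
#' @param fdr FDR threshold for the frequently-mutated flag.
#' @return data.frame as in [re_burden()], one row per gene.
#' @export
creag_burden <- function(matrix, rates, creags, fdr = 0.25) {
  if (nrow(creags) == 0L) stop("empty CREAG table")
  if (!all(matrix$sample_ids %in% rates$sample_id))
    stop("mutation matrix contains samples without background rates")
  ind <- matrix$indicator[, match(rates$sample_id, matrix$sample_ids),
                          drop = FALSE]
  ind[is.na(ind)] <- 0L
  s <- integer(nrow(creags))
  for (j in seq_len(nrow(creags))) {
    members <- creags$re_ids[[j]]
    if (length(members) == 0L) stop("CREAG without member REs: ",
                                    creags$gene_id[j])
    rows <- match(members, matrix$re_ids)
    if (anyNA(rows)) stop("CREAG member RE absent from mutation matrix: ",
                          members[which(is.na(rows))[1L]])
    s[j] <- sum(colSums(ind[rows, , drop = FALSE]) > 0)
  }
  burden_core(creags$gene_id, s, creags$n_j, rates, fdr)
}

#' QQ columns for a burden table
#'
#' Adds expected and observed -log10 p columns for QQ plotting of the
#' burden ranking (expected under uniformity at rank i: i / (m + 1)).
#'
#' @param burden A burden data.frame from [re_burden()]/[creag_burden()].
#' @return The table with `neglog10_expected` and `neglog10_observed`.
#' @export
burden_qq <- function(burden) {
  m <- nrow(burden)
  ord <- order(burden$p_value)
  out <- burden[ord, , drop = FALSE]
  out$neglog10_expected <- -log10(seq_len(m) / (m + 1))
  out$neglog10_observed <- -log10(out$p_value)
  rownames(out) <- NULL
  out
}
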