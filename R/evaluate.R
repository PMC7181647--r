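#' Run the burden test end-to-end on an in-memory cohort
#'
#' Convenience wrapper chaining [covered_regions()],
#' [sample_snv_counts()], [background_rates()],
#' [build_mutation_matrix()] and [re_burden()].
#'
#' @param cohort Output of [simulate_cohort()] (or a list with the same
#'   `layout`, `snvs` fields).
#' @param fdr FDR threshold for the FMRE flag.
#' @param nk_mode Numerator mode for [sample_snv_counts()].
#' @return Burden data.frame from [re_burden()].
#' @export
cohort_burden <- function(cohort, fdr = 0.25, nk_mode = "covered") {
  cov <- covered_regions(cohort$layout$res)
  samples <- sprintf("S%03d", seq_len(cohort$config$n_samples))
  counts <- sample_snv_counts(cohort$snvs, cov, samples, mode = nk_mode)
  rates <- background_rates(counts, cov)
  mm <- build_mutation_matrix(cohort$snvs, cohort$layout$res,
                              samples = rates$sample_id)
  re_burden(mm, rates, cohort$layout$res, fdr = fdr)
}

#' Type-I error and false-discovery calibration on null cohorts
#'
#' Simulates cohorts with no hot elements, runs the burden test, and
#' reports the empirical fraction of p-values at or below each alpha plus
#' the per-replicate false-discovery proportion at the given FDR
#' (under the global null every discovery is false).
#'
#' @param config Base [cohort_config()] (its `hot_res` is cleared).
#' @param n_reps Number of seeded replicates.
#' @param alphas Significance levels to calibrate.
#' @param fdr BH threshold whose false-discovery proportion is tracked.
#' @param base_seed Replicate r uses seed `base_seed + r`.
#' @return List with `type1` (named mean rejection rates), `per_rep`
#'   (matrix replicates x alphas), `fdp` (per-replicate FDP), `n_tests`.
#' @export
null_calibration <- function(config = cohort_config(), n_reps = 20,
                             alphas = c(0.01, 0.05), fdr = 0.25,
                             base_seed = 1000) {
  config$hot_res <- NULL
  per_rep <- matrix(NA_real_, n_reps, length(alphas),
                    dimnames = list(NULL, paste0("alpha_", alphas)))
  fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    b <- cohort_burden(simulate_cohort(cfg), fdr = fdr)
    per_rep[r, ] <- vapply(alphas, function(a) mean(b$p_value <= a),
                           numeric(1))
    n_called <- sum(b$q_value <= fdr)
    fdp[r] <- if (n_called > 0) 1 else 0   # all discoveries false under null
  }
  list(type1 = colMeans(per_rep), per_rep = per_rep, fdp = fdp,
       n_tests = config$n_res)
}

#' Spike-in recovery of hot regulatory elements
#'
#' Plants `n_hot` elements with an elevated per-bp rate and reports, per
#' replicate, whether all of them rank within the `top` smallest burden
#' p-values.
#'
#' @param config Base [cohort_config()].
#' @param n_hot Number of hot REs (named `RE_1..RE_n_hot`).
#' @param multiplier Per-bp rate multiplier of the hot REs.
#' @param top Rank threshold.
#' @param n_reps Seeded replicates.
#' @param base_seed Replicate r uses seed `base_seed + r`.
#' @return List with `recovered` (logical per replicate), `rate`
#'   (fraction of replicates with all hot REs in the top ranks), and
#'   `quantile_sep` (per replicate, the fraction of cold REs with a
#'   p-value above the worst hot p-value).
#' @export
spike_recovery <- function(config = cohort_config(), n_hot = 5,
                           multiplier = 20, top = 10, n_reps = 20,
                           base_seed = 2000) {
  hot <- stats::setNames(rep(multiplier, n_hot), paste0("RE_", seq_len(n_hot)))
  recovered <- logical(n_reps)
  quantile_sep <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    args <- unclass(config)
    args$hot_res <- hot
    args$seed <- as.integer(base_seed + r)
    cfg <- do.call(cohort_config, args)
    b <- cohort_burden(simulate_cohort(cfg))
    ranks <- match(names(hot), b$unit_id)     # b is sorted by p
    recovered[r] <- all(ranks <= top)
    worst_hot <- max(b$p_value[ranks])
    cold <- b$p_value[-ranks]
    quantile_sep[r] <- mean(cold > worst_hot)
  }
  list(recovered = recovered, rate = mean(recovered),
       quantile_sep = quantile_sep)
}

#' Recovery of planted RE-gene pairs by the CREAG mapping
#'
#' Runs [build_creags()] on a simulated cohort and scores the retained
#' associations against the generator's planted cognate pairs.
#'
#' @param config A [cohort_config()]; the linkage and noise fields define
#'   the difficulty of the recovery.
#' @param ... Thresholds passed on to [build_creags()].
#' @return List with `precision`, `recall`, `n_retained`, `n_planted`.
#' @export
creag_recovery <- function(config, ...) {
  co <- simulate_cohort(config)
  out <- build_creags(co$layout$res, co$re_signal, co$layout$genes,
                      co$gene_expr, co$layout$tads, ...)
  key <- function(d) paste(d$re_id, d$gene_id)
  planted <- key(co$layout$cognates)
  retained <- key(out$associations)
  tp <- sum(retained %in% planted)
  list(precision = if (length(retained)) tp / length(retained) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       n_retained = length(retained), n_planted = length(planted))
}
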