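#' Active TF-binding sites: those overlapping H3K27ac peaks
#'
#' @param tfbs [regulatory_set()] of binding sites.
#' @param peaks [regulatory_set()] of active-chromatin peaks.
#' @return The subset of `tfbs` overlapping at least one peak by >= 1 bp.
#' @export
active_sites <- function(tfbs, peaks) {
  hit <- unique(overlaps(tfbs, peaks)$query)
  out <- tfbs[sort(hit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "element_class") <- attr(tfbs, "element_class")
  class(out) <- class(tfbs)
  out
}

#' Mutation enrichment over a set of TF-binding sites
#'
#' Observed: the number of sites carrying at least one SNV in any sample.
#' Expected: under the cohort's background model, the sum over sites of
#' the probability that the site is mutated in at least one sample,
#' `1 - prod_k (1 - hit_probability(p_k, width))`. The fold change is
#' observed/expected and the p-value is the Poisson-binomial upper tail of
#' the observed site count over the per-site mutated probabilities. This
#' site-level null is the package's own definition (the same machinery as
#' the RE burden test, with sites as units) and is recorded as such in
#' the output.
#'
#' @param sites [regulatory_set()] of (typically active) binding sites.
#' @param snvs Filtered SNV data frame.
#' @param rates Per-sample rates from [background_rates()].
#' @return List with `n_sites`, `observed`, `expected`, `fc`, `p_value`,
#'   `site_probs` (per-site mutated probabilities) and `model`.
#' @export
tfbs_enrichment <- function(sites, snvs, rates) {
  if (nrow(sites) == 0L) stop("no binding sites supplied")
  w <- interval_width(sites)
  # P(site i mutated in >= 1 sample): complements multiply over samples
  site_probs <- vapply(w, function(wi)
    -expm1(sum(log1p(-hit_probability(rates$p_k, wi)))), numeric(1))
  pts <- data.frame(chrom = snvs$chrom, start = snvs$pos,
                    end = snvs$pos + 1)
  observed <- length(unique(overlaps(pts, sites)$subject))
  expected <- sum(site_probs)
  fc <- if (expected == 0) {
    if (observed > 0) Inf else NA_real_
  } else observed / expected
  p <- if (all(site_probs < 1)) pbd_tail(site_probs, observed) else {
    # saturated sites are certain hits; condition the tail on them
    sat <- sum(site_probs >= 1)
    rest <- site_probs[site_probs < 1]
    if (length(rest) == 0L || observed <= sat) 1
    else pbd_tail(rest, observed - sat)
  }
  list(n_sites = nrow(sites), observed = observed, expected = expected,
       fc = fc, p_value = p,
       site_probs = site_probs,
       model = "PBD upper tail over per-site mutated probabilities")
}

#' Full per-TF enrichment record (all sites and active sites)
#'
#' @param tf_name TF label for the report.
#' @param tfbs All binding sites for the TF.
#' @param peaks Active-chromatin peaks defining which sites are active.
#' @param snvs Filtered SNV data frame.
#' @param rates Per-sample rates from [background_rates()].
#' @return One-row data.frame (`tf_name`, `n_sites`, `n_active`,
#'   `n_sites_mutated`, `n_active_mutated`, `observed`, `expected`, `fc`,
#'   `p_value`).
#' @export
tfbs_report <- function(tf_name, tfbs, peaks, snvs, rates) {
  act <- active_sites(tfbs, peaks)
  pts <- data.frame(chrom = snvs$chrom, start = snvs$pos,
                    end = snvs$pos + 1)
  n_sites_mut <- length(unique(overlaps(pts, tfbs)$subject))
  enr <- tfbs_enrichment(act, snvs, rates)
  data.frame(tf_name = tf_name, n_sites = nrow(tfbs), n_active = nrow(act),
             n_sites_mutated = n_sites_mut,
             n_active_mutated = enr$observed, observed = enr$observed,
             expected = enr$expected, fc = enr$fc, p_value = enr$p_value,
             stringsAsFactors = FALSE)
}

#' Assign super-enhancers to their highest expressed overlapping gene
#'
#' Expression per gene is summarized as the mean CPM across samples;
#' genes absent from the expression matrix count as 0 (noted in a
#' message). Ties break lexicographically by gene id.
#'
#' @param ses [regulatory_set()] of super-enhancers.
#' @param genes [regulatory_set()] of genes.
#' @param expr [signal_matrix()] of expression (genes x samples).
#' @return data.frame (`se_id`, `gene_id`, `expression`), one row per SE
#'   with at least one overlapping gene.
#' @export
assign_se_genes <- function(ses, genes, expr) {
  mean_expr <- rowMeans(expr)
  ge <- mean_expr[match(genes$name, names(mean_expr))]
  if (anyNA(ge)) {
    message(sum(is.na(ge)), " gene(s) without expression treated as 0")
    ge[is.na(ge)] <- 0
  }
  ov <- overlaps(ses, genes)
  rows <- list()
  for (s in unique(ov$query)) {
    gi <- ov$subject[ov$query == s]
    e <- ge[gi]
    best <- gi[order(-e, genes$name[gi])][1L]
    rows[[length(rows) + 1L]] <- data.frame(
      se_id = ses$name[s], gene_id = genes$name[best],
      expression = ge[best], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(se_id = character(0), gene_id = character(0),
                    expression = numeric(0))
  rownames(out) <- NULL
  out
}

# internal: unweighted KS-style running-sum enrichment score of a gene set
# along a ranking (maximum positive deviation)
gsea_score <- function(ranked_genes, gene_set) {
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit); n <- length(ranked_genes)
  if (nh == 0L || nh == n) stop("gene set must be a proper subset of the ranking")
  step <- ifelse(hit, 1 / nh, -1 / (n - nh))
  max(cumsum(step))
}

#' Enrichment of a gene set at the top of the burden ranking
#'
#' GSEA-style unweighted running-sum (Kolmogorov-Smirnov form) statistic
#' of membership (e.g. super-enhancer-associated genes) along the CREAG
#' burden ranking sorted by p-value, with a label-permutation p-value
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`.
#'
#' @param burden CREAG burden table from [creag_burden()] (sorted or not;
#'   it is ranked by `p_value` internally).
#' @param se_genes Character vector of member genes (e.g. SE-associated).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return List with `score`, `p_value`, `n_genes`, `n_set`, `n_perm`,
#'   `model`.
#' @export
se_creag_enrichment <- function(burden, se_genes, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ranked <- burden$unit_id[order(burden$p_value, burden$unit_id)]
  inset <- intersect(se_genes, ranked)
  if (length(inset) == 0L)
    stop("gene set disjoint from the ranked genes")
  obs <- gsea_score(ranked, inset)
  with_substream(seed, "gsea-perm", {
    perm <- vapply(seq_len(n_perm), function(i)
      gsea_score(ranked, sample(ranked, length(inset))), numeric(1))
    p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  })
  list(score = obs, p_value = p, n_genes = length(ranked),
       n_set = length(inset), n_perm = n_perm,
       model = "unweighted KS running sum, label permutation")
}
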