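# cache of permutation matrices for the exact Spearman null (n <= 8)
.perm_cache <- new.env(parent = emptyenv())

# internal: all permutations of 1..n as an n! x n matrix
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perm <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm(v[-i]))))
  }
  m <- perm(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' One-sided Spearman correlation test (positive association)
#'
#' Computes rho on average-ranked data (midranks for ties) and the
#' upper-tail probability of at least as positive an association. For
#' n <= 8 the p-value is exact, by enumeration of all n! rank
#' permutations (ties handled correctly since midranks are permuted);
#' for larger n the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 df is used.
#'
#' @param x,y Equal-length numeric vectors (n >= 4), not constant.
#' @return List with `rho` and `p_one_sided`.
#' @export
spearman_one_sided <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2) * sum((ry - mean(ry))^2))
    rho_perm <- (matrix(ry[perms], nrow(perms)) %*% cx -
                   0) / denom                 # ry permuted; means cancel
    p <- mean(rho_perm >= rho - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p_one_sided = p)
}

#' Map REs to target genes and assemble CREAGs
#'
#' For every RE/gene pair sharing a TAD (RE midpoint and gene start both
#' inside one common TAD interval) and closer than `max_distance`
#' (RE midpoint to gene start), the one-sided Spearman correlation of RE
#' activity against gene expression across samples is computed. Pairs with
#' `rho > rho_min` and `p < p_max` are retained; retained pairs are
#' grouped by gene into CREAGs whose pseudo-RE width `n_j` is the sum of
#' member RE widths (plus the gene's annotated promoter width when a
#' promoter set is supplied, matched by name).
#'
#' @param res [regulatory_set()] of REs.
#' @param re_signal [signal_matrix()] of RE activity (REs x samples).
#' @param genes [regulatory_set()] of genes.
#' @param gene_expr [signal_matrix()] of expression (genes x samples).
#' @param tads [regulatory_set()] of TADs.
#' @param rho_min Correlation threshold (default 0.4, exclusive).
#' @param p_max One-sided p-value threshold (default 0.05, exclusive).
#' @param max_distance Maximum RE-midpoint-to-gene-start distance in bp
#'   (default 500 kb, exclusive).
#' @param promoters Optional [regulatory_set()] of annotated promoters
#'   named by gene; their widths are added to `n_j`.
#' @param merge_overlaps If `TRUE`, overlapping member intervals are
#'   merged before summing `n_j` (the default sums raw widths).
#' @return List with `associations` (data.frame `re_id`, `gene_id`,
#'   `rho`, `p_one_sided`, `distance`, `tad_id`) and `creags`
#'   (data.frame `gene_id`, `n_res`, `re_ids` list-column, `n_j`).
#' @export
build_creags <- function(res, re_signal, genes, gene_expr, tads,
                         rho_min = 0.4, p_max = 0.05, max_distance = 5e5,
                         promoters = NULL, merge_overlaps = FALSE) {
  shared <- intersect(colnames(re_signal), colnames(gene_expr))
  if (length(shared) < 4L)
    stop("alignment error: fewer than 4 shared sample columns")
  re_signal <- re_signal[, shared, drop = FALSE]
  gene_expr <- gene_expr[, shared, drop = FALSE]
  if (!all(res$name %in% rownames(re_signal)))
    stop("alignment error: REs missing from the signal matrix")
  if (!all(genes$name %in% rownames(gene_expr)))
    stop("alignment error: genes missing from the expression matrix")
  re_mid <- interval_midpoint(res)
  re_pts <- data.frame(chrom = res$chrom, start = re_mid, end = re_mid + 1)
  gene_pts <- data.frame(chrom = genes$chrom, start = genes$start,
                         end = genes$start + 1)
  re_tad <- overlaps(re_pts, tads)
  gene_tad <- overlaps(gene_pts, tads)
  assoc <- list()
  for (t in unique(re_tad$subject)) {
    ris <- re_tad$query[re_tad$subject == t]
    gis <- gene_tad$query[gene_tad$subject == t]
    for (g in gis) {
      d <- abs(re_mid[ris] - genes$start[g])
      for (k in which(d < max_distance)) {
        r <- ris[k]
        ct <- spearman_one_sided(re_signal[res$name[r], ],
                                 gene_expr[genes$name[g], ])
        if (ct$rho > rho_min && ct$p_one_sided < p_max)
          assoc[[length(assoc) + 1L]] <- data.frame(
            re_id = res$name[r], gene_id = genes$name[g],
            rho = ct$rho, p_one_sided = ct$p_one_sided,
            distance = d[k], tad_id = tads$name[t],
            stringsAsFactors = FALSE)
      }
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc)
    else data.frame(re_id = character(0), gene_id = character(0),
                    rho = numeric(0), p_one_sided = numeric(0),
                    distance = numeric(0), tad_id = character(0))
  associations <- associations[order(associations$gene_id,
                                     associations$re_id), , drop = FALSE]
  rownames(associations) <- NULL
  creags <- creags_from_associations(associations, res, promoters,
                                     merge_overlaps)
  list(associations = associations, creags = creags)
}

# internal: group retained associations by gene and compute n_j
creags_from_associations <- function(associations, res, promoters = NULL,
                                     merge_overlaps = FALSE) {
  if (nrow(associations) == 0L)
    return(data.frame(gene_id = character(0), n_res = integer(0),
                      re_ids = I(list()), n_j = numeric(0)))
  byg <- split(associations$re_id, associations$gene_id)
  gene_id <- names(byg)
  n_j <- vapply(seq_along(byg), function(j) {
    members <- res[match(byg[[j]], res$name), , drop = FALSE]
    if (!is.null(promoters)) {
      pr <- promoters[promoters$name == gene_id[j], , drop = FALSE]
      members <- rbind(members[, c("chrom", "start", "end", "name")],
                       pr[, c("chrom", "start", "end", "name")])
    }
    if (merge_overlaps) {
      red <- GenomicRanges::reduce(as_gr(members))
      sum(GenomicRanges::width(red))
    } else sum(members$end - members$start)
  }, numeric(1))
  out <- data.frame(gene_id = gene_id, n_res = lengths(byg),
                    n_j = n_j, stringsAsFactors = FALSE)
  out$re_ids <- unname(byg)
  out[, c("gene_id", "n_res", "re_ids", "n_j")]
}

#' Summary statistics of a CREAG catalog
#'
#' @param creags CREAG table from [build_creags()].
#' @param associations Association table from [build_creags()].
#' @return List with `n_associations`, `n_genes`, `n_res`,
#'   `median_res_per_creag`, `mean_genes_per_re`.
#' @export
creag_summary <- function(creags, associations) {
  if (nrow(associations) == 0L) stop("no associations to summarize")
  list(n_associations = nrow(associations),
       n_genes = length(unique(associations$gene_id)),
       n_res = length(unique(associations$re_id)),
       median_res_per_creag = stats::median(creags$n_res),
       mean_genes_per_re =
         mean(table(associations$re_id)))
}
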