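#' Configuration for a synthetic tumor cohort
#'
#' The generator produces a toy genome whose statistical structure matches
#' what the burden analysis assumes: TADs tiling each chromosome, genes and
#' ~1 kb regulatory elements (REs) nested inside TADs, per-sample somatic
#' SNVs falling uniformly within the RE-covered fraction of the genome at a
#' per-sample background rate, a handful of optional "hot" REs with an
#' elevated per-bp rate, and an H3K27ac-activity / expression matrix pair
#' in which each gene's planted cognate REs share a latent per-sample
#' factor with the gene.
#'
#' Defaults describe a cohort of 50 tumors over a 2 x 5 Mb genome with 10
#' TADs, 40 genes and 500 REs of mean width 1 kb (about 5% genome
#' coverage). Per-sample rates are drawn uniformly from
#' `background_rate_range`; the default `[1e-5, 1e-3]` spans per-sample SNV
#' counts of roughly 5 to 500 over the ~0.5 Mb covered toy genome, the same
#' several-orders-of-magnitude spread seen in real whole-genome cohorts.
#'
#' @param n_samples Number of tumors.
#' @param genome_length Chromosome length in bp (all chromosomes equal).
#' @param n_chromosomes Number of chromosomes.
#' @param n_tads Total number of TADs (distributed over chromosomes).
#' @param n_genes Total number of genes.
#' @param n_res Total number of regulatory elements.
#' @param re_width_mean Mean RE width in bp.
#' @param background_rate_range Length-2 numeric, low/high per-bp per-sample
#'   mutation probability.
#' @param hot_res Named numeric vector: RE name -> rate multiplier (> 1),
#'   or an unnamed count n meaning "the first n REs" with `hot_multiplier`.
#' @param hot_multiplier Multiplier used when `hot_res` is given as a count.
#' @param re_gene_link_strength Weight in \[0,1\] of the shared latent
#'   factor between a gene and its cognate REs.
#' @param noise_sd Standard deviation of the independent noise added to
#'   both the activity and the expression latent variables.
#' @param res_per_gene Cognate REs planted per gene (subject to layout
#'   feasibility).
#' @param gene_width Gene body width in bp.
#' @param seed Integer master seed; every output is a pure function of the
#'   configuration including this seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 50, genome_length = 5e6,
                          n_chromosomes = 2, n_tads = 10, n_genes = 40,
                          n_res = 500, re_width_mean = 1000,
                          background_rate_range = c(1e-5, 1e-3),
                          hot_res = NULL, hot_multiplier = 20,
                          re_gene_link_strength = 0.9, noise_sd = 0.3,
                          res_per_gene = 2, gene_width = 1000, seed = 1) {
  cfg <- list(n_samples = n_samples, genome_length = genome_length,
              n_chromosomes = n_chromosomes, n_tads = n_tads,
              n_genes = n_genes, n_res = n_res,
              re_width_mean = re_width_mean,
              background_rate_range = background_rate_range,
              hot_res = hot_res, hot_multiplier = hot_multiplier,
              re_gene_link_strength = re_gene_link_strength,
              noise_sd = noise_sd, res_per_gene = res_per_gene,
              gene_width = gene_width, seed = as.integer(seed))
  counts <- c("n_samples", "n_chromosomes", "n_tads", "n_genes", "n_res")
  for (f in counts)
    if (cfg[[f]] < 1) stop("configuration error: ", f, " must be >= 1")
  if (cfg$n_tads > cfg$n_genes)
    stop("configuration error: n_tads must not exceed n_genes")
  r <- cfg$background_rate_range
  if (length(r) != 2 || r[1] <= 0 || r[1] > r[2] || r[2] >= 1)
    stop("configuration error: need 0 < low <= high < 1 background rates")
  if (cfg$re_gene_link_strength < 0 || cfg$re_gene_link_strength > 1)
    stop("configuration error: re_gene_link_strength must be in [0,1]")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  mult <- hot_multipliers(cfg)
  if (length(mult) && any(mult <= 1))
    stop("configuration error: hot multipliers must be > 1")
  if (length(mult) && max(mult) * r[2] >= 1)
    stop("configuration error: rate x multiplier >= 1")
  class(cfg) <- "cohort_config"
  cfg
}

# internal: named multiplier vector from the two hot_res spellings
hot_multipliers <- function(config) {
  h <- config$hot_res
  if (is.null(h) || length(h) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(h)) && length(h) == 1L && h == round(h) && h >= 1) {
    nm <- paste0("RE_", seq_len(h))
    return(stats::setNames(rep(config$hot_multiplier, h), nm))
  }
  if (is.null(names(h))) stop("hot_res must be named or a single count")
  stats::setNames(as.numeric(h), names(h))
}

# internal: derived sub-seed for a named stage, keeping 32-bit range
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

# internal: run expr under a stage-specific seed, restoring the caller's RNG
with_substream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stage))
  expr
}

# internal: place m non-overlapping intervals of the given widths uniformly
# inside [lo, hi); returns 0-based starts
place_intervals <- function(lo, hi, widths) {
  m <- length(widths)
  if (m == 0L) return(numeric(0))
  free <- (hi - lo) - sum(widths)
  if (free < m) stop("configuration error: infeasible interval packing")
  cuts <- sort(sample.int(free, m))
  gaps <- diff(c(0, cuts))
  lo + cumsum(gaps) + cumsum(c(0, widths[-m]))
}

#' Simulate the toy genome layout
#'
#' TADs tile each chromosome exactly; every gene and RE lies wholly inside
#' one TAD; each gene's planted cognate REs share its TAD and lie within
#' 500 kb of the gene start.
#'
#' @param config A [cohort_config()].
#' @return List with `tads`, `genes`, `res` ([regulatory_set()]s) and
#'   `cognates` (data.frame `gene_id`, `re_id` of planted pairs).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_substream(config$seed, "genome", {
    L <- config$genome_length
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    # distribute TADs over chromosomes as evenly as possible
    per_chrom <- rep(config$n_tads %/% config$n_chromosomes,
                     config$n_chromosomes)
    extra <- config$n_tads %% config$n_chromosomes
    if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    if (any(per_chrom < 1L))
      stop("configuration error: fewer TADs than chromosomes")
    tad_rows <- list()
    for (i in seq_along(chroms)) {
      k <- per_chrom[i]
      bounds <- if (k > 1L) sort(sample(seq(2e5, L - 2e5, by = 1e4), k - 1L))
                else numeric(0)
      b <- c(0, bounds, L)
      tad_rows[[i]] <- data.frame(chrom = chroms[i], start = b[-length(b)],
                                  end = b[-1L])
    }
    tads <- do.call(rbind, tad_rows)
    tads <- regulatory_set(tads$chrom, tads$start, tads$end,
                           paste0("TAD_", seq_len(nrow(tads))),
                           element_class = "tad")
    # assign genes and REs to TADs proportionally to TAD width
    tadw <- interval_width(tads)
    assign_units <- function(n) {
      raw <- tadw / sum(tadw) * n
      k <- floor(raw)
      rem <- n - sum(k)
      if (rem > 0) {
        ord <- order(raw - k, decreasing = TRUE)
        k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
      }
      k
    }
    genes_per_tad <- pmax(assign_units(config$n_genes), 1L)
    while (sum(genes_per_tad) > config$n_genes) {
      i <- which.max(genes_per_tad)
      genes_per_tad[i] <- genes_per_tad[i] - 1L
    }
    res_per_tad <- assign_units(config$n_res)
    gene_rows <- list(); re_rows <- list()
    for (t in seq_len(nrow(tads))) {
      ng <- genes_per_tad[t]; nr <- res_per_tad[t]
      gw <- rep(config$gene_width, ng)
      rw <- pmax(200, round(stats::rnorm(nr, config$re_width_mean,
                                         config$re_width_mean / 4)))
      widths <- c(gw, rw)
      ord <- sample.int(length(widths))
      starts <- place_intervals(tads$start[t], tads$end[t], widths[ord])
      starts <- starts[order(ord)]  # back to gene-then-RE order
      if (ng) gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(chrom = tads$chrom[t], start = starts[seq_len(ng)],
                   end = starts[seq_len(ng)] + gw, tad = t)
      if (nr) re_rows[[length(re_rows) + 1L]] <-
        data.frame(chrom = tads$chrom[t], start = starts[ng + seq_len(nr)],
                   end = starts[ng + seq_len(nr)] + rw, tad = t)
    }
    gdf <- do.call(rbind, gene_rows)
    rdf <- do.call(rbind, re_rows)
    genes <- regulatory_set(gdf$chrom, gdf$start, gdf$end,
                            paste0("G_", seq_len(nrow(gdf))),
                            element_class = "gene")
    res <- regulatory_set(rdf$chrom, rdf$start, rdf$end,
                          paste0("RE_", seq_len(nrow(rdf))),
                          element_class = "enhancer")
    # plant cognate REs: same TAD, midpoint within 450 kb of gene start,
    # each RE serving at most one gene
    re_mid <- interval_midpoint(res)
    taken <- rep(FALSE, nrow(res))
    cg <- list()
    for (g in seq_len(nrow(genes))) {
      cand <- which(rdf$tad == gdf$tad[g] & !taken &
                    abs(re_mid - gdf$start[g]) <= 4.5e5)
      if (!length(cand)) next
      pick <- cand[sample.int(length(cand),
                              min(config$res_per_gene, length(cand)))]
      taken[pick] <- TRUE
      cg[[length(cg) + 1L]] <- data.frame(gene_id = genes$name[g],
                                          re_id = res$name[pick])
    }
    cognates <- if (length(cg)) do.call(rbind, cg)
                else data.frame(gene_id = character(0), re_id = character(0))
    rownames(cognates) <- NULL
    list(tads = tads, genes = genes, res = res, cognates = cognates)
  })
}

#' Simulate RE activity and gene expression matrices
#'
#' For every planted cognate pair, the RE activity latent variable is
#' `link * l_g + noise` and the gene expression latent is `l_g + noise`,
#' where `l_g` is a per-gene standard-normal factor over samples; all
#' other REs are pure noise. Latents are exponentiated (lognormal
#' marginals) so values are non-negative; since downstream association is
#' rank-based, the monotone marginal transform is immaterial.
#'
#' @param layout Output of [simulate_genome()].
#' @param config The same [cohort_config()].
#' @return List with `re_signal` and `gene_expr` ([signal_matrix()]s,
#'   features x samples).
#' @export
simulate_activity_expression <- function(layout, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_substream(config$seed, "signal", {
    ns <- config$n_samples
    samples <- sprintf("S%03d", seq_len(ns))
    ngene <- nrow(layout$genes); nre <- nrow(layout$res)
    latent <- matrix(stats::rnorm(ngene * ns), ngene, ns,
                     dimnames = list(layout$genes$name, samples))
    gene_lat <- latent + config$noise_sd * stats::rnorm(ngene * ns)
    re_lat <- matrix(stats::rnorm(nre * ns), nre, ns,
                     dimnames = list(layout$res$name, samples))
    link <- config$re_gene_link_strength
    if (nrow(layout$cognates)) {
      gi <- match(layout$cognates$gene_id, layout$genes$name)
      ri <- match(layout$cognates$re_id, layout$res$name)
      re_lat[ri, ] <- link * latent[gi, , drop = FALSE] +
        config$noise_sd *
        matrix(stats::rnorm(length(ri) * ns), length(ri), ns)
    }
    re_signal <- signal_matrix(exp(log(10) + re_lat))
    gene_expr <- signal_matrix(exp(log(100) + gene_lat))
    list(re_signal = re_signal, gene_expr = gene_expr)
  })
}

#' Simulate somatic SNVs over the covered (RE) regions
#'
#' Each sample draws a background per-bp rate uniformly from
#' `background_rate_range`; within every RE each base mutates
#' independently at that rate times the RE's hot multiplier. Counts are
#' drawn Poisson per (RE, sample) and placed uniformly without replacement
#' inside the RE (equivalent to redrawing collisions), which matches the
#' per-bp Bernoulli model to well below the simulated rates.
#'
#' @param layout Output of [simulate_genome()].
#' @param config The same [cohort_config()].
#' @return List with `snvs` (data.frame `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `rates` (data.frame `sample_id`, `rate`,
#'   `n_snvs` realized count).
#' @export
simulate_snvs <- function(layout, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_substream(config$seed, "snv", {
    ns <- config$n_samples
    samples <- sprintf("S%03d", seq_len(ns))
    r <- config$background_rate_range
    rate <- stats::runif(ns, r[1], r[2])
    mult <- rep(1, nrow(layout$res))
    hm <- hot_multipliers(config)
    if (length(hm)) {
      idx <- match(names(hm), layout$res$name)
      if (anyNA(idx)) stop("hot_res names not present in layout: ",
                           paste(names(hm)[is.na(idx)], collapse = ", "))
      mult[idx] <- hm
    }
    if (max(rate) * max(mult) >= 1)
      stop("configuration error: rate x multiplier >= 1")
    w <- interval_width(layout$res)
    lambda <- outer(w * mult, rate)          # RE x sample expected counts
    counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    counts <- pmin(counts, matrix(w, nrow(counts), ncol(counts)))
    nz <- which(counts > 0, arr.ind = TRUE)
    bases <- c("A", "C", "G", "T")
    if (nrow(nz)) {
      cnt <- counts[nz]
      re_i <- rep(nz[, 1L], cnt)
      sm_i <- rep(nz[, 2L], cnt)
      cell <- rep(seq_len(nrow(nz)), cnt)
      off <- floor(stats::runif(length(re_i)) * w[re_i])
      # redraw collisions within a (sample, RE) cell until positions unique
      repeat {
        dup <- duplicated(paste(cell, off))
        if (!any(dup)) break
        off[dup] <- floor(stats::runif(sum(dup)) * w[re_i[dup]])
      }
      ref_i <- sample.int(4L, length(re_i), replace = TRUE)
      alt_i <- (ref_i - 1L + sample.int(3L, length(re_i),
                                        replace = TRUE)) %% 4L + 1L
      snvs <- data.frame(sample_id = samples[sm_i],
                         chrom = layout$res$chrom[re_i],
                         pos = layout$res$start[re_i] + off,
                         ref = bases[ref_i], alt = bases[alt_i],
                         stringsAsFactors = FALSE)
    } else {
      snvs <- data.frame(sample_id = character(0), chrom = character(0),
                         pos = numeric(0), ref = character(0),
                         alt = character(0))
    }
    snvs <- snvs[order(snvs$sample_id, snvs$chrom, snvs$pos), , drop = FALSE]
    rownames(snvs) <- NULL
    n_snvs <- as.integer(table(factor(snvs$sample_id, levels = samples)))
    list(snvs = snvs,
         rates = data.frame(sample_id = samples, rate = rate,
                            n_snvs = n_snvs))
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genome()],
#' [simulate_activity_expression()] and [simulate_snvs()] under the
#' config's seed.
#'
#' @param config A [cohort_config()].
#' @return List with `config`, `layout`, `re_signal`, `gene_expr`, `snvs`,
#'   `rates`.
#' @export
simulate_cohort <- function(config) {
  layout <- simulate_genome(config)
  sig <- simulate_activity_expression(layout, config)
  mut <- simulate_snvs(layout, config)
  list(config = config, layout = layout, re_signal = sig$re_signal,
       gene_expr = sig$gene_expr, snvs = mut$snvs, rates = mut$rates)
}

#' Write a simulated cohort to disk in the package's exchange formats
#'
#' Emits the exact on-disk formats the readers consume (BED for intervals,
#' TSV for SNVs and matrices) plus a JSON manifest recording the
#' configuration and seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cohort$layout$tads, file.path(dir, "tads.bed"))
  write_bed(cohort$layout$genes, file.path(dir, "genes.bed"))
  write_bed(cohort$layout$res, file.path(dir, "res.bed"))
  write_snvs(cohort$snvs, file.path(dir, "snvs.tsv"))
  write_signal_matrix(cohort$re_signal, file.path(dir, "re_signal.tsv"),
                      feature_col = "re_id")
  write_signal_matrix(cohort$gene_expr, file.path(dir, "gene_expr.tsv"),
                      feature_col = "gene_id")
  utils::write.table(cohort$layout$cognates,
                     file.path(dir, "cognates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$rates, file.path(dir, "sample_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
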