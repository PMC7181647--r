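#' Percentage of a count ratio at the requested display precision
#'
#' `100 * numerator / denominator`, rounded half-up. Display precision is
#' presentation, not analysis: both integer and one-decimal renderings
#' occur in cohort summaries.
#'
#' @param numerator,denominator Counts with `0 <= numerator <= denominator`
#'   and `denominator > 0`.
#' @param digits Decimal places of the percentage (default 1; use 0 for
#'   integer display).
#' @return The rounded percentage as a number.
#' @examples
#' ratio_report(109, 169)      # 64.5
#' ratio_report(36, 169, 0)    # 21
#' @export
ratio_report <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must be in [0, denominator]")
  pct <- 100 * numerator / denominator
  scale <- 10^digits
  floor(pct * scale + 0.5) / scale
}

#' Cohort summary of named counts and ratios
#'
#' @param counts Named numeric vector of counts (summed into `total`).
#' @param ratios Named list of `c(numerator, denominator)` pairs.
#' @param digits Percentage precision passed to [ratio_report()].
#' @return List with `counts`, `total`, and a `ratios` data.frame
#'   (`name`, `numerator`, `denominator`, `percent`).
#' @export
cohort_summary <- function(counts = NULL, ratios = NULL, digits = 1) {
  out <- list()
  if (!is.null(counts)) {
    out$counts <- counts
    out$total <- sum(counts)
  }
  if (!is.null(ratios)) {
    out$ratios <- data.frame(
      name = names(ratios),
      numerator = vapply(ratios, `[`, numeric(1), 1L),
      denominator = vapply(ratios, `[`, numeric(1), 2L),
      percent = vapply(ratios, function(r)
        ratio_report(r[1L], r[2L], digits), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Threshold bundle for a pipeline run
#'
#' All defaults are the analysis' standard operating points: association
#' gates rho > 0.4, one-sided p < 0.05, distance < 500 kb; expression
#' fold-change bounds 2 and 0.5 with at least 2 mutated samples; FMRE
#' calling at FDR 0.25 (0.10 is the conventional stricter flag).
#'
#' @param rho_min,p_max,max_distance CREAG association gates.
#' @param fc_hi,fc_lo,min_mut Expression-association settings.
#' @param fdr FMRE/CREAG FDR threshold.
#' @param nk_mode `"covered"` (numerator restricted to covered regions,
#'   matching the denominator) or `"global"`.
#' @param n_perm Permutations for the SE enrichment.
#' @return Named list of thresholds.
#' @export
run_thresholds <- function(rho_min = 0.4, p_max = 0.05, max_distance = 5e5,
                           fc_hi = 2, fc_lo = 0.5, min_mut = 2,
                           fdr = 0.25, nk_mode = "covered", n_perm = 1000) {
  th <- list(rho_min = rho_min, p_max = p_max, max_distance = max_distance,
             fc_hi = fc_hi, fc_lo = fc_lo, min_mut = min_mut, fdr = fdr,
             nk_mode = nk_mode, n_perm = n_perm)
  num <- unlist(th[c("rho_min", "p_max", "max_distance", "fc_hi", "fc_lo",
                     "min_mut", "fdr", "n_perm")])
  if (any(num <= 0)) stop("thresholds must be positive")
  th
}

# internal: stage file requirements for pre-flight validation
stage_inputs <- function(stage) {
  switch(stage,
         filter = "snvs.tsv",
         matrix = c("snvs.tsv", "res.bed"),
         creags = c("res.bed", "genes.bed", "tads.bed", "re_signal.tsv",
                    "gene_expr.tsv"),
         burden = c("snvs.tsv", "res.bed"),
         expression = c("snvs.tsv", "res.bed", "gene_expr.tsv"),
         tfbs = c("tfbs.bed", "snvs.tsv", "res.bed"),
         se = c("ses.bed", "genes.bed", "gene_expr.tsv"),
         character(0))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end on a cohort directory
#'
#' Consumes the on-disk exchange formats written by [write_cohort()] (or
#' assembled by hand: BED interval sets, a TSV SNV table, TSV signal and
#' expression matrices) and executes the enabled stages in dependency
#' order: filter -> matrix -> creags -> burden -> expression -> tfbs/se.
#' Optional exclusion sets (`coding.bed`, `blacklist.bed`,
#' `chip_artifact.bed`) and optional TFBS/SE inputs (`tfbs.bed`,
#' `ses.bed`) are used when present. Every stage writes TSV outputs into
#' `out_dir`; a JSON manifest records the configuration, seed, input
#' checksums and package version. All inputs are validated before any
#' stage executes; a stage failure aborts with the failing stage named,
#' retaining earlier outputs.
#'
#' @param input_dir Directory of input files.
#' @param out_dir Output directory (created).
#' @param stages Character vector of stages to run (default: all; `tfbs`
#'   and `se` are skipped quietly when their inputs are absent).
#' @param thresholds A [run_thresholds()] bundle.
#' @param seed Integer seed (SE-enrichment permutations).
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         stages = c("filter", "matrix", "creags", "burden",
                                    "expression", "tfbs", "se"),
                         thresholds = run_thresholds(), seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  optional <- c("tfbs", "se")
  stages <- c(setdiff(stages, optional),
              intersect(stages, optional)[
                vapply(intersect(stages, optional), function(s)
                  all(file.exists(file.path(input_dir, stage_inputs(s)))),
                  logical(1))])
  # pre-flight: every enabled stage's inputs must resolve before anything runs
  for (s in stages) {
    need <- file.path(input_dir, stage_inputs(s))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("pre-flight: stage '", s, "' requires missing input(s): ",
           paste(basename(miss), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(f) file.path(input_dir, f)
  outp <- function(f) file.path(out_dir, f)
  opt_bed <- function(f, class) {
    if (file.exists(inp(f))) read_bed(inp(f), element_class = class)
    else NULL
  }
  res <- list(thresholds = thresholds, seed = seed)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("filter" %in% stages) run_stage("filter", function() {
    snvs <- read_snvs(inp("snvs.tsv"), "tsv")
    filt <- filter_snvs(snvs,
                        coding = opt_bed("coding.bed", "coding"),
                        blacklist = opt_bed("blacklist.bed", "blacklist"),
                        chip_artifact = opt_bed("chip_artifact.bed",
                                                "blacklist"))
    res$snvs <<- filt
    write_snvs(filt, outp("filtered_snvs.tsv"))
    write_tsv(as.data.frame(multiplicity_summary(filt)),
              outp("multiplicity.tsv"))
  })
  if (is.null(res$snvs)) res$snvs <- read_snvs(inp("snvs.tsv"), "tsv")

  if (any(c("matrix", "burden", "expression", "tfbs") %in% stages)) {
    res$res_set <- read_bed(inp("res.bed"), element_class = "enhancer")
    cov <- covered_regions(res$res_set)
    samples <- sort(unique(res$snvs$sample_id))
    counts <- sample_snv_counts(res$snvs, cov, samples,
                                mode = thresholds$nk_mode)
    res$rates <- background_rates(counts, cov)
    write_tsv(res$rates, outp("sample_rates.tsv"))
  }

  if ("matrix" %in% stages) run_stage("matrix", function() {
    res$matrix <<- build_mutation_matrix(res$snvs, res$res_set,
                                         samples = res$rates$sample_id)
    ind <- data.frame(re_id = res$matrix$re_ids,
                      as.data.frame(res$matrix$indicator),
                      check.names = FALSE)
    write_tsv(ind, outp("mutation_indicator.tsv"))
  })

  if ("creags" %in% stages) run_stage("creags", function() {
    tads <- read_bed(inp("tads.bed"), element_class = "tad",
                     name_prefix = "TAD")
    genes <- read_bed(inp("genes.bed"), element_class = "gene",
                      name_prefix = "G")
    re_signal <- read_signal_matrix(inp("re_signal.tsv"))
    gene_expr <- read_signal_matrix(inp("gene_expr.tsv"))
    res$creag_map <<- build_creags(
      res$res_set %||% read_bed(inp("res.bed")), re_signal, genes,
      gene_expr, tads, rho_min = thresholds$rho_min,
      p_max = thresholds$p_max, max_distance = thresholds$max_distance)
    write_tsv(res$creag_map$associations, outp("associations.tsv"))
    ct <- res$creag_map$creags
    flat <- data.frame(gene_id = ct$gene_id, n_res = ct$n_res,
                       n_j = ct$n_j,
                       re_ids = vapply(ct$re_ids, paste, "",
                                       collapse = ","))
    write_tsv(flat, outp("creags.tsv"))
  })

  if ("burden" %in% stages) run_stage("burden", function() {
    if (is.null(res$matrix))
      res$matrix <<- build_mutation_matrix(res$snvs, res$res_set,
                                           samples = res$rates$sample_id)
    res$burden_re <<- re_burden(res$matrix, res$rates, res$res_set,
                                fdr = thresholds$fdr)
    write_tsv(burden_qq(res$burden_re), outp("burden_re.tsv"))
    if (!is.null(res$creag_map) && nrow(res$creag_map$creags)) {
      res$burden_creag <<- creag_burden(res$matrix, res$rates,
                                        res$creag_map$creags,
                                        fdr = thresholds$fdr)
      write_tsv(burden_qq(res$burden_creag), outp("burden_creag.tsv"))
    }
  })

  if ("expression" %in% stages) run_stage("expression", function() {
    gene_expr <- read_signal_matrix(inp("gene_expr.tsv"))
    if (is.null(res$creag_map) || nrow(res$creag_map$associations) == 0L)
      return(invisible(NULL))
    if (is.null(res$matrix))
      res$matrix <<- build_mutation_matrix(res$snvs, res$res_set,
                                           samples = res$rates$sample_id)
    pairs_re <- data.frame(unit_id = res$creag_map$associations$re_id,
                           gene_id = res$creag_map$associations$gene_id)
    res$expr_re <<- mutation_expression_scan(
      res$matrix, gene_expr, pairs_re, min_mut = thresholds$min_mut,
      fc_hi = thresholds$fc_hi, fc_lo = thresholds$fc_lo)
    write_tsv(res$expr_re, outp("expr_assoc_re.tsv"))
    cm <- creag_indicator(res$matrix, res$creag_map$creags)
    pairs_cg <- data.frame(unit_id = res$creag_map$creags$gene_id,
                           gene_id = res$creag_map$creags$gene_id)
    res$expr_creag <<- mutation_expression_scan(
      cm, gene_expr, pairs_cg, min_mut = thresholds$min_mut,
      fc_hi = thresholds$fc_hi, fc_lo = thresholds$fc_lo)
    write_tsv(res$expr_creag, outp("expr_assoc_creag.tsv"))
    skew <- do.call(rbind, lapply(
      list(re = res$expr_re, creag = res$expr_creag), function(d) {
        n_over <- sum(d$direction == "over")
        n_under <- sum(d$direction == "under")
        data.frame(n_over = n_over, n_under = n_under,
                   p_skew = if (n_over + n_under >= 1)
                     skew_test(n_over, n_under) else NA_real_)
      }))
    skew <- data.frame(level = rownames(skew), skew, row.names = NULL)
    write_tsv(skew, outp("skew.tsv"))
  })

  if ("tfbs" %in% stages) run_stage("tfbs", function() {
    tfbs <- read_bed(inp("tfbs.bed"), element_class = "tfbs",
                     name_prefix = "TFBS")
    res$tfbs <<- tfbs_report("TF", tfbs, res$res_set, res$snvs, res$rates)
    write_tsv(res$tfbs, outp("tfbs_enrichment.tsv"))
  })

  if ("se" %in% stages) run_stage("se", function() {
    ses <- read_bed(inp("ses.bed"), element_class = "se",
                    name_prefix = "SE")
    genes <- read_bed(inp("genes.bed"), element_class = "gene",
                      name_prefix = "G")
    gene_expr <- read_signal_matrix(inp("gene_expr.tsv"))
    res$se_assign <<- assign_se_genes(ses, genes, gene_expr)
    write_tsv(res$se_assign, outp("se_assignments.tsv"))
    if (!is.null(res$burden_creag) &&
        length(intersect(res$se_assign$gene_id,
                         res$burden_creag$unit_id))) {
      enr <- se_creag_enrichment(res$burden_creag,
                                 unique(res$se_assign$gene_id),
                                 n_perm = thresholds$n_perm, seed = seed)
      res$se_enrich <<- enr
      write_tsv(data.frame(score = enr$score, p_value = enr$p_value,
                           n_genes = enr$n_genes, n_set = enr$n_set,
                           n_perm = enr$n_perm),
                outp("se_enrichment.tsv"))
    }
  })

  inputs <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    package = "reburden",
    version = as.character(utils::packageVersion("reburden")),
    seed = seed, stages = stages, thresholds = thresholds,
    config_hash = substr(tools::md5sum(
      write_tsv(data.frame(unlist(thresholds)),
                file.path(tempdir(), "thresholds.tsv")))[[1]], 1, 12),
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs))))
  jsonlite::write_json(manifest, outp("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
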