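#' Filter SNVs against coding, blacklist and ChIP-artifact regions
#'
#' Removes every SNV whose 1-bp interval `[pos, pos+1)` overlaps any
#' exclusion set (half-open containment, consistent with the global BED
#' convention). Empty or `NULL` exclusion sets are legal; removal counts
#' per category are recorded in the `"removed"` attribute and messaged.
#' The operation is idempotent.
#'
#' @param snvs SNV data frame (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param coding,blacklist,chip_artifact Optional [regulatory_set()]s of
#'   regions to exclude.
#' @return Filtered SNV data frame with attribute `removed` (named counts).
#' @export
filter_snvs <- function(snvs, coding = NULL, blacklist = NULL,
                        chip_artifact = NULL) {
  sets <- list(coding = coding, blacklist = blacklist,
               chip_artifact = chip_artifact)
  removed <- c(coding = 0L, blacklist = 0L, chip_artifact = 0L)
  keep <- rep(TRUE, nrow(snvs))
  if (nrow(snvs)) {
    pts <- data.frame(chrom = snvs$chrom, start = snvs$pos,
                      end = snvs$pos + 1)
    for (nm in names(sets)) {
      s <- sets[[nm]]
      if (is.null(s) || nrow(s) == 0L) next
      hit <- unique(overlaps(pts, s)$query)
      removed[nm] <- sum(keep[hit])
      keep[hit] <- FALSE
    }
  }
  out <- snvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (sum(removed) > 0)
    message("filter_snvs removed ", sum(removed), " SNV(s) (",
            paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  attr(out, "removed") <- removed
  out
}

#' Per-sample filtered SNV counts (the burden numerator n_k)
#'
#' By default counts only SNVs falling inside the covered regions, so the
#' numerator of the background rate matches its denominator (the covered
#' width). `mode = "global"` counts every filtered SNV instead.
#'
#' @param snvs Filtered SNV data frame.
#' @param covered A [covered_regions()] object or a [regulatory_set()]
#'   (required for the default mode).
#' @param samples Optional character vector of cohort sample ids, so that
#'   samples with zero SNVs are still reported.
#' @param mode `"covered"` (default) or `"global"`.
#' @return data.frame with columns `sample_id`, `n_k`.
#' @export
sample_snv_counts <- function(snvs, covered = NULL, samples = NULL,
                              mode = c("covered", "global")) {
  mode <- match.arg(mode)
  if (mode == "covered") {
    if (is.null(covered)) stop("covered regions required for mode='covered'")
    iv <- if (inherits(covered, "covered_regions")) covered$intervals
          else covered
    pts <- data.frame(chrom = snvs$chrom, start = snvs$pos,
                      end = snvs$pos + 1)
    inside <- unique(overlaps(pts, iv)$query)
    snvs <- snvs[inside, , drop = FALSE]
  }
  if (is.null(samples)) samples <- sort(unique(snvs$sample_id))
  tab <- table(factor(snvs$sample_id, levels = samples))
  data.frame(sample_id = samples, n_k = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Build the sample-by-RE mutation matrix
#'
#' The indicator is 1 iff the sample has at least one filtered SNV
#' overlapping the RE; `snv_count` holds the raw overlapping counts. A
#' sample with several SNVs in one RE contributes 1 to that RE's
#' mutated-sample count.
#'
#' @param snvs Filtered SNV data frame.
#' @param res [regulatory_set()] of regulatory elements (unique names).
#' @param samples Optional cohort sample ids (columns); defaults to the
#'   samples present in `snvs`.
#' @return A `mutation_matrix`: list with binary `indicator` and integer
#'   `snv_count` matrices (REs x samples).
#' @export
build_mutation_matrix <- function(snvs, res, samples = NULL) {
  if (anyDuplicated(res$name)) stop("duplicate RE names")
  if (is.null(samples)) samples <- sort(unique(snvs$sample_id))
  if (nrow(snvs) && !all(snvs$sample_id %in% samples))
    stop("SNVs carry sample ids absent from 'samples'")
  cnt <- matrix(0L, nrow(res), length(samples),
                dimnames = list(res$name, samples))
  if (nrow(snvs)) {
    pts <- data.frame(chrom = snvs$chrom, start = snvs$pos,
                      end = snvs$pos + 1)
    ov <- overlaps(pts, res)
    if (nrow(ov)) {
      tab <- table(factor(ov$subject, levels = seq_len(nrow(res))),
                   factor(match(snvs$sample_id[ov$query], samples),
                          levels = seq_along(samples)))
      cnt[] <- as.integer(tab)
    }
  }
  out <- list(indicator = (cnt >= 1L) * 1L, snv_count = cnt,
              re_ids = rownames(cnt), sample_ids = colnames(cnt))
  class(out) <- "mutation_matrix"
  out
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d element(s) x %d sample(s), %d SNV(s)\n",
              length(x$re_ids), length(x$sample_ids), sum(x$snv_count)))
  invisible(x)
}

#' Position-multiplicity summary of SNVs
#'
#' Tabulates, for each multiplicity m, the number of genomic positions
#' carrying exactly m SNV records (positions keyed by chrom and pos).
#' Two conservation identities hold by construction and are asserted on
#' every call: the multiplicity-weighted sum of position counts equals the
#' number of SNVs, and the plain sum equals the number of distinct
#' positions.
#'
#' @param snvs SNV data frame.
#' @return data.frame (`multiplicity`, `n_positions`) of class
#'   `multiplicity_table`.
#' @export
multiplicity_summary <- function(snvs) {
  if (nrow(snvs) == 0L) {
    out <- data.frame(multiplicity = integer(0), n_positions = integer(0))
  } else {
    per_pos <- table(paste(snvs$chrom, snvs$pos))
    tab <- table(as.integer(per_pos))
    out <- data.frame(multiplicity = as.integer(names(tab)),
                      n_positions = as.integer(tab))
  }
  stopifnot(sum(out$multiplicity * out$n_positions) == nrow(snvs))
  class(out) <- c("multiplicity_table", "data.frame")
  out
}

#' Totals implied by a multiplicity table
#'
#' @param tab A `multiplicity_table` (or data.frame with `multiplicity`,
#'   `n_positions`).
#' @return List with `total_snvs` (= sum m * count) and `total_positions`
#'   (= sum count).
#' @export
multiplicity_totals <- function(tab) {
  list(total_snvs = sum(tab$multiplicity * tab$n_positions),
       total_positions = sum(tab$n_positions))
}
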