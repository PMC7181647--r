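#' Read a BED3/BED4 file into a regulatory_set
#'
#' Tab-separated, no header; `track`/`browser`/`#` lines are skipped.
#' Coordinates follow the BED convention (0-based, half-open). When the
#' fourth (name) column is absent, names are auto-generated as
#' `"<name_prefix>_<i>"`.
#'
#' @param path Path to the BED file.
#' @param element_class Class tag recorded on the returned set.
#' @param name_prefix Prefix for auto-generated names.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return A [regulatory_set()].
#' @export
read_bed <- function(path, element_class = "enhancer", name_prefix = "RE",
                     chrom_style = "asis") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(regulatory_set(character(0), numeric(0), numeric(0),
                          element_class = element_class))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         " in ", path, ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", lineno[which(is.na(start) | is.na(end))[1L]],
         " in ", path, ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval on line ", lineno[bad[1L]], " in ", path,
         ": start >= end")
  name <- vapply(seq_along(fields), function(i)
    if (nf[i] >= 4L) fields[[i]][[4L]]
    else paste0(name_prefix, "_", i), "")
  out <- regulatory_set(chrom, start, end, name,
                        element_class = element_class,
                        name_prefix = name_prefix)
  normalize_chroms(out, chrom_style)
}

#' Write a regulatory_set as BED4
#' @param x A [regulatory_set()] or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE), x$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read somatic SNVs from a VCF or a simple tabular dialect
#'
#' Only biallelic single-base substitutions are retained; indel and
#' multi-nucleotide records are dropped with a message stating the count.
#' Duplicate records (same sample, chrom, pos, alt) are removed with a
#' warning. Internally all positions are 0-based; VCF positions (1-based)
#' are converted on load.
#'
#' The TSV dialect has five columns `sample_id`, `chrom`, `pos` (0-based),
#' `ref`, `alt`, with an optional header row.
#'
#' @param path Path to the variant file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_id Sample label for VCF input. Defaults to the single
#'   genotype column name when present, otherwise the file basename.
#' @param chrom_style Passed to [normalize_chroms()].
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per SNV).
#' @export
read_snvs <- function(path, dialect = c("tsv", "vcf"), sample_id = NULL,
                      chrom_style = "asis") {
  if (!is.character(dialect) ||
      !all(dialect %in% c("tsv", "vcf")))
    stop("unknown SNV dialect: ", paste(dialect, collapse = ","))
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("SNV file not found: ", path)
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    fix <- if (is.matrix(fix)) as.data.frame(fix, stringsAsFactors = FALSE)
           else as.data.frame(as.list(fix), stringsAsFactors = FALSE)
    if (is.null(sample_id)) {
      gt_samples <- tryCatch(colnames(vcf@gt)[-1], error = function(e) NULL)
      sample_id <- if (length(gt_samples) == 1L) gt_samples
                   else sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
    df <- data.frame(sample_id = sample_id, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS) - 1, ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    has_header <- grepl("sample", tolower(first))
    df <- utils::read.delim(path, header = has_header,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!has_header) {
      if (ncol(df) < 5L) stop("TSV SNV file needs 5 columns")
      df <- df[, 1:5]
      names(df) <- c("sample_id", "chrom", "pos", "ref", "alt")
    }
    df <- df[, c("sample_id", "chrom", "pos", "ref", "alt")]
    df$pos <- as.numeric(df$pos)
  }
  bases <- c("A", "C", "G", "T")
  is_snv <- df$ref %in% bases & df$alt %in% bases & df$ref != df$alt
  if (any(!is_snv))
    message(sum(!is_snv), " non-SNV record(s) dropped from ", basename(path))
  df <- df[is_snv, , drop = FALSE]
  key <- paste(df$sample_id, df$chrom, df$pos, df$alt, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate SNV record(s) removed from ",
            basename(path))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  normalize_chroms(df, chrom_style)
}

#' Write SNVs in the package's tabular dialect
#' @param snvs SNV data frame as returned by [read_snvs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snvs <- function(snvs, path) {
  df <- snvs[, c("sample_id", "chrom", "pos", "ref", "alt")]
  df$pos <- format(df$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a signal matrix (H3K27ac score or expression CPM)
#'
#' @param values Numeric matrix, features x samples; all finite and >= 0.
#' @param row_ids,col_ids Optional identifiers (default: dimnames).
#' @return Numeric matrix with class `signal_matrix` and unique dimnames.
#' @export
signal_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids))
    stop("signal matrix needs row and column identifiers")
  if (anyDuplicated(row_ids)) stop("duplicated row identifiers")
  if (anyDuplicated(col_ids)) stop("duplicated column identifiers")
  if (any(!is.finite(values))) stop("signal values must be finite")
  if (any(values < 0)) stop("signal values must be >= 0")
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  class(values) <- c("signal_matrix", class(values))
  values
}

#' Read a TSV feature-by-sample matrix
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path Path to the TSV file.
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  signal_matrix(as.matrix(df))
}

#' Write a signal matrix as TSV
#' @param x A [signal_matrix()] (or plain matrix with dimnames).
#' @param path Output path.
#' @param feature_col Name for the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path, feature_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
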