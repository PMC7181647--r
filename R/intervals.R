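#' Construct a set of regulatory intervals
#'
#' The common currency of all overlap logic in the package: a data frame of
#' genomic intervals in 0-based, half-open (BED) coordinates with unique
#' names and an element class tag.
#'
#' @param chrom Character vector of chromosome labels (non-empty strings),
#'   or a data frame with columns `chrom`, `start`, `end` (and optionally
#'   `name`), in which case the remaining coordinate arguments are ignored.
#' @param start Integer vector, 0-based inclusive start (bp).
#' @param end Integer vector, 0-based exclusive end (bp); must be > `start`.
#' @param name Optional character vector of unique identifiers. Auto-named
#'   `"<prefix>_<i>"` when absent.
#' @param element_class One of `"enhancer"`, `"promoter"`, `"tad"`,
#'   `"tfbs"`, `"blacklist"`, `"coding"`, `"gene"`, `"se"`.
#' @param name_prefix Prefix used when auto-generating names.
#' @return A `regulatory_set`: data.frame with columns `chrom`, `start`,
#'   `end`, `name` and attribute `element_class`.
#' @examples
#' regulatory_set("chr1", 100, 200, "E1")
#' @export
regulatory_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                           element_class = "enhancer", name_prefix = "RE") {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    name <- if ("name" %in% names(df)) as.character(df$name) else name
    chrom <- as.character(df$chrom)
    start <- df$start
    end <- df$end
  }
  element_class <- match.arg(
    element_class,
    c("enhancer", "promoter", "tad", "tfbs", "blacklist", "coding",
      "gene", "se"))
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0L) {
    if (any(!nzchar(chrom)) || anyNA(chrom))
      stop("chromosome labels must be non-empty")
    if (anyNA(start) || anyNA(end))
      stop("interval coordinates must not be NA")
    bad <- which(end <= start)
    if (length(bad))
      stop("invalid interval (start >= end) at row ", bad[1L],
           ": ", chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]])
    if (any(start < 0))
      stop("negative start coordinate")
  }
  if (is.null(name)) {
    name <- if (n > 0L) paste0(name_prefix, "_", seq_len(n)) else character(0)
  } else {
    name <- as.character(name)
    if (length(name) != n) stop("name must match the number of intervals")
    if (anyDuplicated(name))
      stop("duplicated interval names: ",
           paste(unique(name[duplicated(name)])[1:3], collapse = ", "))
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = name, stringsAsFactors = FALSE)
  attr(out, "element_class") <- element_class
  class(out) <- c("regulatory_set", "data.frame")
  out
}

#' @export
print.regulatory_set <- function(x, ...) {
  cat(sprintf("regulatory_set of %d %s interval(s), total width %s bp\n",
              nrow(x), attr(x, "element_class"),
              format(sum(interval_width(x)), big.mark = ",")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Interval widths in base pairs
#' @param x A `regulatory_set` or a data frame with `start`/`end`.
#' @return Numeric vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Midpoints of intervals (floor of the arithmetic mean, 0-based)
#' @inheritParams interval_width
#' @return Numeric vector of midpoint coordinates.
#' @export
interval_midpoint <- function(x) floor((x$start + x$end - 1) / 2)

# internal: GRanges view of a half-open interval frame (1-based closed inside)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair of intervals sharing at least one base on the same
#' chromosome, under the half-open convention (abutting intervals do not
#' overlap). Backed by an interval-tree search; a quadratic scan gives the
#' same answer on any input.
#'
#' @param query,subject `regulatory_set`s or data frames with
#'   `chrom`/`start`/`end`.
#' @return data.frame with integer columns `query` and `subject` (row
#'   indices), sorted by query then subject.
#' @examples
#' a <- regulatory_set("chr1", 100, 200)
#' b <- regulatory_set("chr1", 150, 250)
#' overlaps(a, b)
#' @export
overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(0), subject = integer(0)))
  hits <- GenomicRanges::findOverlaps(as_gr(query), as_gr(subject))
  out <- data.frame(query = S4Vectors::queryHits(hits),
                    subject = S4Vectors::subjectHits(hits))
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Normalize chromosome naming style
#'
#' Chromosome labels are compared as exact strings everywhere in the
#' package ("chr1" != "1"); this switch converts between the UCSC-style
#' "chr" prefix and bare labels so that inputs from different callers can
#' be reconciled explicitly rather than silently.
#'
#' @param x A `regulatory_set`, an SNV data frame (column `chrom`), or a
#'   character vector of chromosome labels.
#' @param style `"asis"` (no change), `"chr"` (ensure prefix) or
#'   `"plain"` (strip prefix).
#' @return Object of the same shape with relabelled chromosomes.
#' @export
normalize_chroms <- function(x, style = c("asis", "chr", "plain")) {
  style <- match.arg(style)
  fix <- function(v) {
    if (style == "chr") ifelse(grepl("^chr", v), v, paste0("chr", v))
    else if (style == "plain") sub("^chr", "", v)
    else v
  }
  if (is.character(x)) return(fix(x))
  x$chrom <- fix(x$chrom)
  x
}
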