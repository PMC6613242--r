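#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (BED convention) used for every BED-style feature in the package:
#' open-chromatin peaks, promoters, compartment segments, TADs, switch
#' regions.  Any 1-based input dialect is converted at the reader boundary.
#'
#' @param chrom character chromosome names (taken verbatim; no "chr"
#'   normalisation).
#' @param start,end integer base-pair coordinates, `0 <= start < end`.
#' @param strand one of `"+", "-", "."` per interval.
#' @param id optional character identifiers.
#' @return a `data.frame` with class `genomic_intervals` and columns
#'   `chrom`, `start`, `end`, `strand`, `id`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = ".", id = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  stopifnot(length(end) == n)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  id <- rep_len(as.character(id), n)
  if (n > 0) {
    if (any(start < 0)) stop("interval start must be >= 0")
    if (any(end <= start)) stop("interval end must be > start")
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  }
  structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               strand = strand, id = id, stringsAsFactors = FALSE),
    class = c("genomic_intervals", "data.frame")
  )
}

as_granges <- function(x) {
  # internal bridge: 0-based half-open -> 1-based closed IRanges
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Read a BED file (3-6 columns)
#'
#' @param path path to a tab-separated BED file; `track`/`browser`/`#`
#'   header lines are skipped.
#' @return [genomic_intervals()] in file order; strand `"."` when absent.
#' @details Malformed lines (non-integer coordinates, `end <= start`)
#'   raise an error naming the offending line number.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(genomic_intervals())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 3)) {
    stop("BED line ", idx[which(ncol < 3)[1]], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) stop("BED line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop("BED line ", idx[bad[1]], ": invalid coordinates (end <= start or start < 0)")
  }
  id <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  id[ncol < 4] <- NA_character_
  strand <- rep(".", length(idx))
  has6 <- ncol >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-", ".")] <- "."
  genomic_intervals(chrom, start, end, strand, id)
}

#' Write intervals as BED
#'
#' @param x [genomic_intervals()].
#' @param path output path.
#' @param score optional numeric score column (written as column 5).
#' @export
write_bed <- function(x, path, score = NULL) {
  df <- data.frame(x$chrom, format_num(x$start), format_num(x$end))
  if (!all(is.na(x$id)) || !is.null(score)) {
    df$name <- ifelse(is.na(x$id), ".", x$id)
  }
  if (!is.null(score)) {
    df$score <- format_num(score)
    df$strand <- x$strand
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  out[is.na(x)] <- "NA"
  out
}

#' Report all overlapping interval pairs
#'
#' A pair `(i, j)` is reported iff intervals `a[i]` and `b[j]` share at
#' least 1 bp under half-open arithmetic, so abutting intervals
#' (`[0,100)` vs `[100,150)`) do not overlap.
#'
#' @param a,b [genomic_intervals()] on the same coordinate convention.
#' @return a `data.frame` with columns `a_idx`, `b_idx` (row indices into
#'   `a` and `b`), sorted by `(a_idx, b_idx)`.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b), minoverlap = 1L)
  out <- data.frame(a_idx = S4Vectors::queryHits(hits),
                    b_idx = S4Vectors::subjectHits(hits))
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

#' Merge overlapping or abutting intervals
#'
#' Mirrors `bedtools merge` with a configurable gap tolerance (default 0 bp:
#' overlapping and book-ended intervals are merged, as when building a
#' "masterBED" union peak set across conditions).
#'
#' @param x [genomic_intervals()].
#' @param gap maximum bp gap between intervals that are still merged
#'   (0 merges abutting intervals).
#' @return merged [genomic_intervals()], sorted by `(chrom, start, end)`.
#' @export
merge_intervals <- function(x, gap = 0) {
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1)
  gr <- GenomicRanges::sort(gr)
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1,
                    GenomicRanges::end(gr))
}

#' Which intervals contain each point position?
#'
#' @param chrom,pos vectors of point positions (0-based).
#' @param x [genomic_intervals()].
#' @return integer vector: for each point, the row index of the first
#'   containing interval in `x` (`start <= pos < end`), or `NA`.
#' @export
point_in_interval <- function(chrom, pos, x) {
  n <- length(pos)
  out <- rep(NA_integer_, n)
  if (nrow(x) == 0 || n == 0) return(out)
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, width = 1))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, as_granges(x), select = "first")
  )
  out[] <- hits
  out
}

#' Interval midpoints
#' @param x [genomic_intervals()].
#' @return numeric midpoints in bp.
#' @export
interval_midpoint <- function(x) (x$start + x$end) / 2
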