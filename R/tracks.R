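#' Construct a binned per-chromosome track
#'
#' One value per fixed-width bin along a chromosome, with a boolean mask of
#' excluded bins.  Used for PC1 compartment scores, insulation scores and
#' gene-density tracks.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param values numeric vector, one per bin; masked bins are stored as `NA`.
#' @param mask logical vector (`TRUE` = excluded); defaults to
#'   `!is.finite(values)`.
#' @return list of class `binned_track` with fields `chrom`, `bin_size`,
#'   `values`, `mask`, `n_bins`.
#' @export
binned_track <- function(chrom, bin_size, values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- !is.finite(values)
  stopifnot(length(mask) == length(values), bin_size >= 1)
  values[mask] <- NA_real_
  structure(list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
                 values = values, mask = as.logical(mask),
                 n_bins = length(values)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d bins of %g bp (%d masked)\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$mask)))
  invisible(x)
}

# bin start coordinates (0-based) of a track
bin_starts <- function(track) (seq_len(track$n_bins) - 1) * track$bin_size

#' Write a binned track as bedGraph
#'
#' One line per unmasked bin (`chrom  start  end  value`); values are
#' written at 6 significant digits and round-trip bit-exactly at that
#' precision with [read_bedgraph()].  A fully masked track produces a file
#' with no data lines.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  keep <- !track$mask
  starts <- bin_starts(track)[keep]
  lines <- sprintf("%s\t%s\t%s\t%s",
                   track$chrom, format_num(starts),
                   format_num(starts + track$bin_size),
                   sprintf("%.6g", track$values[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a binned track
#'
#' @param path bedGraph path.
#' @param chrom chromosome to extract.
#' @param bin_size bin width in bp (must match the writer's grid).
#' @param n_bins number of bins of the full track; bins absent from the
#'   file are masked.
#' @return a [binned_track()].
#' @export
read_bedgraph <- function(path, chrom, bin_size, n_bins) {
  lines <- readLines(path)
  values <- rep(NA_real_, n_bins)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ch <- vapply(fields, `[[`, "", 1L)
    st <- as.numeric(vapply(fields, `[[`, "", 2L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    sel <- ch == chrom
    if (any(st[sel] %% bin_size != 0)) {
      stop("bedGraph interval start not on the ", bin_size, "-bp bin grid")
    }
    values[st[sel] / bin_size + 1] <- val[sel]
  }
  binned_track(chrom, bin_size, values)
}
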