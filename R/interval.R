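#' Genomic interval (1-based, inclusive)
#'
#' Internal coordinate convention for the whole package: 1-based inclusive
#' spans, as printed in VCF and in the mapping literature. Interval length is
#' defined as `end - start` (not `end - start + 1`): the published bounds of
#' the bovine chromosome 19 autozygosity interval (26,848,700-27,529,700)
#' subtract to exactly 681,000 bp, i.e. 681 kb.
#'
#' @param chrom chromosome label (e.g. `"chr19"`).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return an object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr19", 26848700, 27529700)
#' interval_length_kb(iv) # 681
#' @export
genomic_interval <- function(chrom, start, end) {
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L) {
    stop("genomic_interval() takes scalar arguments", call. = FALSE)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    stop("invalid interval: need 1 <= start <= end", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x a `genomic_interval`.
#' @export
interval_length_bp <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' @rdname genomic_interval
#' @export
interval_length_kb <- function(x) interval_length_bp(x) / 1000

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%g kb)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), interval_length_kb(x)))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))
}

#' Parse an interval string "chr:start-end" (1-based inclusive)
#' @param spec a string such as `"chr19:26848700-27529700"`.
#' @return a `genomic_interval`.
#' @export
parse_interval <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse interval specification '%s' (expected chr:start-end)",
                 spec), call. = FALSE)
  }
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Convert an interval to BED convention (0-based, half-open)
#'
#' BED rows use 0-based half-open coordinates; the conversion from the
#' internal 1-based inclusive convention subtracts 1 from the start only.
#'
#' @param x a `genomic_interval`.
#' @return a one-row `data.frame` with `chrom`, `start`, `end`.
#' @export
as_bed <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  data.frame(chrom = x$chrom, start = x$start - 1, end = x$end)
}

in_interval <- function(chrom, pos, interval) {
  chrom == interval$chrom & pos >= interval$start & pos <= interval$end
}
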