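#' Splice donor position weight matrix
#'
#' A 4 x 9 base-probability matrix over the canonical donor window: three
#' exonic positions (-3..-1) followed by six intronic positions (+1..+6).
#' Columns must each sum to 1; scoring is log-odds against a uniform 0.25
#' background, so a uniform matrix scores 0 for every window.
#'
#' @param mat numeric 4 x 9 matrix, rownames `A, C, G, T`, columns summing
#'   to 1 (tolerance 1e-6), all entries positive.
#' @return object of class `splice_pwm`.
#' @export
splice_pwm <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L, ncol(mat) == 9L)
  if (is.null(rownames(mat)) || !identical(sort(rownames(mat)), c("A", "C", "G", "T"))) {
    stop("pwm rows must be named A, C, G, T", call. = FALSE)
  }
  mat <- mat[c("A", "C", "G", "T"), ]
  if (any(mat <= 0)) stop("pwm entries must be positive (smooth zeros)", call. = FALSE)
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop("each pwm column must sum to 1", call. = FALSE)
  }
  structure(list(mat = mat), class = "splice_pwm")
}

#' Default donor-site matrix (canonical mammalian consensus)
#'
#' Base frequencies approximating the classical mammalian donor consensus
#' (consensus window `CAG|GTAAGT`; the invariant GT dinucleotide is smoothed
#' to 0.997 to keep log-odds finite). This is a generic donor model, not the
#' matrix of any external scoring server, so absolute scores are not
#' comparable with server outputs - only score differences between ref and
#' alt windows are meaningful for ranking disruption.
#'
#' @return a [splice_pwm()].
#' @export
default_donor_pwm <- function() {
  m <- rbind(
    A = c(0.33, 0.60, 0.08, 0.001, 0.001, 0.59, 0.71, 0.06, 0.17),
    C = c(0.37, 0.13, 0.04, 0.001, 0.001, 0.03, 0.08, 0.06, 0.19),
    G = c(0.18, 0.14, 0.81, 0.997, 0.001, 0.35, 0.12, 0.82, 0.18),
    T = c(0.12, 0.13, 0.07, 0.001, 0.997, 0.03, 0.09, 0.06, 0.46))
  splice_pwm(m)
}

#' Score a 9-base donor window against a PWM
#'
#' `score = sum_i log2(pwm[base_i, i] / 0.25)`. Higher scores indicate a
#' stronger match to the donor consensus.
#'
#' @param window 9-character string over `A, C, G, T` (exonic -3..-1 then
#'   intronic +1..+6).
#' @param pwm a [splice_pwm()]; default [default_donor_pwm()].
#' @return numeric log-odds score (bits).
#' @export
score_donor_site <- function(window, pwm = default_donor_pwm()) {
  stopifnot(inherits(pwm, "splice_pwm"))
  window <- toupper(window)
  if (nchar(window) != 9L) {
    stop("scoring error: donor window must be 9 bases", call. = FALSE)
  }
  bases <- strsplit(window, "")[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf("scoring error: ambiguous base '%s' at window position %d",
                 bases[bad[1L]], bad[1L]), call. = FALSE)
  }
  sum(log2(pwm$mat[cbind(match(bases, rownames(pwm$mat)), seq_len(9L))] / 0.25))
}

#' Donor score change between reference and alternate windows
#'
#' @param ref_window,alt_window 9-base windows (same junction, ref and alt
#'   allele).
#' @inheritParams score_donor_site
#' @return list with `ref`, `alt`, `delta` (= alt - ref; negative values
#'   mean the variant weakens the donor site).
#' @export
score_donor_delta <- function(ref_window, alt_window, pwm = default_donor_pwm()) {
  r <- score_donor_site(ref_window, pwm)
  a <- score_donor_site(alt_window, pwm)
  list(ref = r, alt = a, delta = a - r)
}
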