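#' Cohort genotype counts
#'
#' Container for the genotype counts of a cohort at a biallelic locus, with
#' `GG` the wild-type homozygote, `AG` the heterozygote and `AA` the
#' homozygote for the alternate (disease) allele.
#'
#' @param n_GG,n_AG,n_AA non-negative integer counts.
#' @param label optional cohort label (breed, age class).
#' @return an object of class `cohort_counts`.
#' @examples
#' cohort_counts(2698, 854, 45, label = "Charolais")
#' @export
cohort_counts <- function(n_GG, n_AG, n_AA, label = NA_character_) {
  for (nm in c("n_GG", "n_AG", "n_AA")) {
    assert_count(get(nm), nm)
  }
  structure(list(n_GG = as.integer(n_GG), n_AG = as.integer(n_AG),
                 n_AA = as.integer(n_AA), label = label),
            class = "cohort_counts")
}

total_count <- function(counts) counts$n_GG + counts$n_AG + counts$n_AA

check_nonempty <- function(counts) {
  if (total_count(counts) == 0L) {
    stop("undefined frequency: cohort has zero animals", call. = FALSE)
  }
}

#' Alternate-allele frequency of a cohort, in percent
#'
#' Computes `100 * (2 n_AA + n_AG) / (2 (n_GG + n_AG + n_AA))` and reports it
#' under both printing conventions used in the field: rounded to one decimal
#' (table style) and to the nearest integer percent (prose style). Ties round
#' half away from zero.
#'
#' @param counts a [cohort_counts()].
#' @return a list with `percent` (exact), `percent_1dp`, `percent_int`.
#' @examples
#' allele_frequency(cohort_counts(2540, 782, 37))$percent_1dp # 12.7
#' allele_frequency(cohort_counts(2698, 854, 45))$percent_int # 13
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  check_nonempty(counts)
  p <- 100 * (2 * counts$n_AA + counts$n_AG) / (2 * total_count(counts))
  list(percent = p,
       percent_1dp = round_half_up(p, 1),
       percent_int = round_half_up(p, 0))
}

#' Fraction of alternate-allele homozygotes in a cohort, in percent
#'
#' @inheritParams allele_frequency
#' @return a list with `percent` (exact) and `percent_1dp`.
#' @examples
#' homozygote_fraction(cohort_counts(2309, 722, 34))$percent_1dp # 1.1
#' @export
homozygote_fraction <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  check_nonempty(counts)
  p <- 100 * counts$n_AA / total_count(counts)
  list(percent = p, percent_1dp = round_half_up(p, 1))
}

#' Genotype-contrast effect ratios
#'
#' Expresses a genotype contrast (e.g. the heterozygote minus wild-type mean
#' difference for a trait) relative to the trait's phenotypic mean (percent,
#' one decimal) and to its phenotypic standard deviation (two decimals).
#'
#' @param contrast contrast in trait units.
#' @param mean phenotypic mean of the trait (non-zero).
#' @param sd phenotypic standard deviation (positive).
#' @return list with `pct_of_mean`, `sd_units` (rounded) and the exact values
#'   `pct_of_mean_exact`, `sd_units_exact`.
#' @examples
#' effect_ratios(1.6, 63, 9.4)    # 2.5% of mean, 0.17 SD
#' effect_ratios(12.5, 618, 45.2) # 2.0% of mean, 0.28 SD
#' @export
effect_ratios <- function(contrast, mean, sd) {
  if (!is.numeric(mean) || mean == 0) stop("domain error: mean must be non-zero", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("domain error: sd must be positive", call. = FALSE)
  pct <- 100 * contrast / mean
  sdu <- contrast / sd
  list(pct_of_mean = round_half_up(pct, 1), sd_units = round_half_up(sdu, 2),
       pct_of_mean_exact = pct, sd_units_exact = sdu)
}

#' Exact one-sided test for a deficit of alternate homozygotes
#'
#' Conditional exact Hardy-Weinberg test in the homozygote-deficit direction.
#' Conditioning on the observed allele counts (nA copies of A among 2n
#' alleles), the number of AA homozygotes under random union of gametes has
#' the Levene distribution
#' `P(n_AA) = n! / (n_GG! n_AG! n_AA!) * 2^n_AG * nA! nG! / (2n)!`;
#' the p-value sums configurations with `n_AA` at or below the observed value.
#' A chi-square test is invalid here because cohorts of interest have empty
#' AA cells (no homozygous animals survive to 30 months).
#'
#' @inheritParams allele_frequency
#' @return list with `p_value`, `observed_AA`, `expected_AA` (conditional
#'   expectation) and the full conditional distribution as a `data.frame`.
#' @export
homozygote_deficit_test <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  check_nonempty(counts)
  n <- total_count(counts)
  nA <- 2L * counts$n_AA + counts$n_AG
  nG <- 2L * n - nA
  aa_max <- nA %/% 2L
  aa_min <- max(0L, nA - n)
  aa <- aa_min:aa_max
  het <- nA - 2L * aa
  gg <- n - aa - het
  logp <- lfactorial(n) - lfactorial(gg) - lfactorial(het) - lfactorial(aa) +
    het * log(2) + lfactorial(nA) + lfactorial(nG) - lfactorial(2L * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pval <- sum(pr[aa <= counts$n_AA])
  list(p_value = pval,
       observed_AA = counts$n_AA,
       expected_AA = sum(aa * pr),
       distribution = data.frame(n_AA = aa, prob = pr))
}

#' Allele-frequency trajectory over age cohorts
#'
#' Applies [allele_frequency()] per cohort (ordered as supplied, e.g. by age)
#' and flags a monotone decline of the integer-percent frequency, the pattern
#' expected when homozygotes are progressively lost from ageing cohorts of a
#' recessive lethal.
#'
#' @param cohorts a list of [cohort_counts()], ordered (e.g. by age).
#' @return list with `table` (one row per cohort) and `declining` (logical:
#'   frequencies non-increasing with at least one strict drop).
#' @export
frequency_trajectory <- function(cohorts) {
  if (length(cohorts) < 1L) stop("need at least one cohort", call. = FALSE)
  rows <- lapply(cohorts, function(cc) {
    f <- allele_frequency(cc)
    data.frame(label = cc$label, n_GG = cc$n_GG, n_AG = cc$n_AG, n_AA = cc$n_AA,
               freq_pct = f$percent, freq_1dp = f$percent_1dp,
               freq_int = f$percent_int)
  })
  tab <- do.call(rbind, rows)
  declining <- length(cohorts) > 1L &&
    all(diff(tab$freq_int) <= 0) && any(diff(tab$freq_int) < 0)
  list(table = tab, declining = declining)
}
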