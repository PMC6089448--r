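#' Summarize paranodal-length measurements by group
#'
#' Per-group sample size, mean, standard error of the mean and range for
#' paranodal immunostaining lengths (micrometres). Groups are typically
#' `control_wt`, `affected_in_lesion` and `affected_out_lesion`.
#'
#' @param measures a `data.frame` with columns `length_um` (positive numeric)
#'   and `group`; an optional `section` column is carried through unchanged.
#' @return a `data.frame` with one row per group: `group`, `n`, `mean`, `se`
#'   (NA when n = 1), `min`, `max`.
#' @export
summarize_groups <- function(measures) {
  if (nrow(measures) == 0L) {
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      se = numeric(), min = numeric(), max = numeric()))
  }
  stopifnot(all(c("length_um", "group") %in% names(measures)))
  if (any(!is.finite(measures$length_um)) || any(measures$length_um <= 0)) {
    stop("lengths must be positive and finite", call. = FALSE)
  }
  out <- lapply(split(measures$length_um, measures$group), function(x) {
    data.frame(n = length(x), mean = mean(x),
               se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
               min = min(x), max = max(x))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' One-way analysis of variance on group measurements
#'
#' Classical fixed-effects one-way ANOVA (between/within sum-of-squares
#' decomposition) on raw lengths, as used to compare paranodal-length groups.
#' A log-scale option exists because lengths are right-skewed; it defaults
#' off so that the default analysis matches the plain variance analysis.
#'
#' @inheritParams summarize_groups
#' @param log_scale analyse `log(length)` instead of raw lengths.
#' @return list with `F`, `df1`, `df2`, `p_value`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
anova_oneway <- function(measures, log_scale = FALSE) {
  stopifnot(all(c("length_um", "group") %in% names(measures)))
  g <- factor(measures$group)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  y <- measures$length_um
  if (log_scale) y <- log(y)
  n <- length(y)
  k <- nlevels(g)
  if (n <= k) stop("total n must exceed the number of groups", call. = FALSE)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tabulate(g)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((y - means[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within <= 0) {
    warning("zero within-group variance; F is infinite")
    return(list(F = Inf, df1 = df1, df2 = df2, p_value = 0,
                ss_between = ss_between, ss_within = ss_within,
                ss_total = ss_between + ss_within))
  }
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
       ss_between = ss_between, ss_within = ss_within,
       ss_total = ss_between + ss_within)
}
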