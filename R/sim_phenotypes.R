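#' Simulate pre-corrected phenotypes under the animal model
#'
#' Draws `y = mu + effect(genotype) + u + e` with polygenic values
#' `u ~ N(0, A * sigma_a2)` (realized through the Cholesky factor of A) and
#' independent residuals `e ~ N(0, sigma_e2)`. Phenotypes are emitted
#' pre-corrected: environmental effects (herd, year, season) are assumed to
#' have been removed upstream, as in national genetic evaluations. An
#' optional additive nuisance layer exists for stress testing and defaults
#' off.
#'
#' @param ped pedigree `data.frame` covering all phenotyped animals.
#' @param A numerator relationship matrix from
#'   [build_numerator_relationship()] (or any conformable PSD matrix with
#'   animal ids as dimnames).
#' @param truth a `sim_truth` (for per-animal genotype classes), or a named
#'   character vector of classes in `{GG, AG, AA}`.
#' @param config a [sim_config()] (variance components, seed).
#' @param mu overall mean (trait units).
#' @param effect named numeric: genotype-class effects relative to GG, e.g.
#'   `c(AG = 1.6, AA = 0)`; missing classes get 0.
#' @param trait trait label for the output table.
#' @param n_nuisance_groups,nuisance_sd optional nuisance layer: animals are
#'   split into this many groups with N(0, sd^2) group effects added; 0
#'   disables (default).
#' @param chol_A optional pre-computed upper Cholesky factor of A (reusing it
#'   across replicate draws avoids refactorizing).
#' @param seed overrides `config$seed` when not NULL.
#' @return `data.frame` with `animal_id`, `trait`, `value`, `genotype`, plus
#'   attribute `components` (the realized `u` and `e` vectors).
#' @export
simulate_phenotypes <- function(ped, A, truth, config, mu = 63,
                                effect = c(AG = 1.6, AA = 0),
                                trait = "muscular_development",
                                n_nuisance_groups = 0L, nuisance_sd = 0,
                                chol_A = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- ped$animal_id
  if (is.null(rownames(A)) || !all(ids %in% rownames(A))) {
    stop("dimension error: A must cover all pedigree animals (named dimnames)",
         call. = FALSE)
  }
  A <- A[ids, ids, drop = FALSE]
  status <- if (inherits(truth, "sim_truth")) truth$carrier_status else truth
  if (!all(ids %in% names(status))) {
    stop("dimension error: genotype classes missing for some animals", call. = FALSE)
  }
  g <- status[ids]
  eff <- setNames(numeric(length(g)), ids)
  for (cl in names(effect)) eff[g == cl] <- effect[[cl]]

  n <- length(ids)
  sa2 <- config$phenotype_sigma_a2
  se2 <- config$phenotype_sigma_e2
  if (is.null(chol_A) && sa2 > 0) {
    chol_A <- chol(A + diag(1e-10, n))
  }
  with_seed(seed %||% config$seed + 2L, {
    u <- if (sa2 > 0) sqrt(sa2) * drop(crossprod(chol_A, rnorm(n))) else numeric(n)
    e <- rnorm(n, sd = sqrt(se2))
    nuis <- 0
    if (n_nuisance_groups > 0L && nuisance_sd > 0) {
      grp <- sample.int(n_nuisance_groups, n, replace = TRUE)
      nuis <- rnorm(n_nuisance_groups, sd = nuisance_sd)[grp]
    }
    y <- mu + eff + u + e + nuis
    out <- data.frame(animal_id = ids, trait = trait, value = as.numeric(y),
                      genotype = unname(g), stringsAsFactors = FALSE)
    attr(out, "components") <- list(u = setNames(as.numeric(u), ids),
                                    e = setNames(e, ids))
    out
  })
}

#' Log-normal parameters matching a target mean and SD
#'
#' Moment matching: `sigma2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma2/2`, so the log-normal has exactly the requested
#' arithmetic mean and standard deviation.
#'
#' @param mean,sd target arithmetic mean and SD (positive).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || !is.numeric(sd) || sd <= 0) {
    stop("configuration error: mean and sd must be positive", call. = FALSE)
  }
  s2 <- log(1 + sd^2 / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate paranodal-length measurements
#'
#' Draws strictly positive, right-skewed lengths (micrometres) from
#' log-normal distributions moment-matched to each group's target mean and
#' SD. Defaults emulate paranodal immunostaining lengths in demyelinating
#' lesions (greatly elongated), outside lesions and in unaffected controls.
#'
#' @param group_specs `data.frame` with columns `group`, `mean`, `sd`, `n`.
#' @param seed integer seed.
#' @return `data.frame` with `length_um`, `group`, `section`.
#' @export
simulate_paranodal_lengths <- function(group_specs = data.frame(
                                         group = c("control_wt",
                                                   "affected_in_lesion",
                                                   "affected_out_lesion"),
                                         mean = c(3.9, 16, 2.1),
                                         sd = c(0.6, 0.8, 0.7),
                                         n = c(155L, 115L, 194L)),
                                       seed = 1L) {
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(group_specs)))
  if (any(group_specs$n < 1L)) stop("configuration error: each group needs n >= 1",
                                    call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_specs)), function(i) {
      sp <- group_specs[i, ]
      lp <- lognormal_params(sp$mean, sp$sd) # errors on non-positive mean/sd
      data.frame(length_um = stats::rlnorm(sp$n, lp$meanlog, lp$sdlog),
                 group = sp$group, section = sprintf("%s_s%04d", sp$group, seq_len(sp$n)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
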