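# shared small dataset for the model tests
mk_assoc_data <- function(seed = 5, n_founders = 10, n_gen = 4, per_gen = 120,
                          effect = c(AG = 1.6, AA = 0), probs = c(.75, .22, .03)) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_gen,
                    n_offspring_per_gen = per_gen, seed = seed)
  ped <- simulate_pedigree(cfg)
  A <- build_numerator_relationship(ped)
  set.seed(seed + 100)
  classes <- setNames(sample(c("GG", "AG", "AA"), nrow(ped), TRUE, probs),
                      ped$animal_id)
  phen <- simulate_phenotypes(ped, A, classes, cfg, effect = effect)
  list(cfg = cfg, ped = ped, A = A, classes = classes,
       y = setNames(phen$value, phen$animal_id))
}

test_that("with sigma_a2 fixed to zero the fit reduces to class means", {
  d <- mk_assoc_data(seed = 3)
  fit <- reml_fit(d$y, d$classes, d$A, fix_sigma_a2_zero = TRUE)
  means <- tapply(d$y, d$classes[names(d$y)], mean)
  expect_equal(fit$mu, unname(means["GG"]))
  expect_equal(unname(fit$beta["AG-GG"]), unname(means["AG"] - means["GG"]))
  expect_equal(unname(fit$beta["AA-GG"]), unname(means["AA"] - means["GG"]))
  expect_equal(fit$sigma_a2, 0)
})

test_that("at a fixed ratio the eigen route equals a dense GLS solve and the sparse MME", {
  d <- mk_assoc_data(seed = 7, per_gen = 60)
  lambda <- 2.5
  fit <- reml_fit(d$y, d$classes, d$A, lambda_fixed = lambda)
  # dense GLS oracle: V = A/lambda + I (up to sigma_e2, which cancels)
  ids <- names(d$y)
  X <- cbind(1, d$classes[ids] == "AG", d$classes[ids] == "AA")
  V <- d$A[ids, ids] / lambda + diag(length(ids))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  expect_equal(unname(c(fit$mu, fit$beta)), unname(drop(beta)), tolerance = 1e-8)
  mme <- solve_mme(d$y, d$classes, d$ped, lambda)
  expect_equal(unname(mme$beta), unname(drop(beta)), tolerance = 1e-8)
})

test_that("the optimizer beats a grid of candidate ratios", {
  d <- mk_assoc_data(seed = 11, per_gen = 60)
  fit <- reml_fit(d$y, d$classes, d$A)
  grid <- seq(log(1e-4), log(1e4), length.out = 60)
  lls <- vapply(grid, fit$profile_fn, numeric(1))
  expect_gte(fit$loglik + 1e-6, max(lls))
})

test_that("an absent genotype class is reported non-estimable, not an error", {
  d <- mk_assoc_data(seed = 13, probs = c(.8, .2, 0))
  expect_false("AA" %in% d$classes)
  fit <- reml_fit(d$y, d$classes, d$A)
  expect_true(is.na(fit$beta["AA-GG"]))
  ct <- genotype_contrasts(fit)
  expect_match(ct$note[ct$contrast == "AA-GG"], "no phenotyped AA")
  expect_false(is.na(fit$beta["AG-GG"]))
})

test_that("contrast equal to 2 SE gives the closed-form two-sided p", {
  d <- mk_assoc_data(seed = 17, per_gen = 80)
  fit <- reml_fit(d$y, d$classes, d$A)
  z <- unname(fit$beta["AG-GG"] / fit$se["AG-GG"])
  expect_equal(unname(fit$p_value["AG-GG"]), 2 * pnorm(-abs(z)))
  # and literally: if the estimate were exactly 2 SE, p ~ 0.0455
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)
})

test_that("planted AG-GG contrast is recovered without material bias (quick study)", {
  cfg <- sim_config(n_founders = 10, n_generations = 4, n_offspring_per_gen = 160,
                    seed = 23)
  ped <- simulate_pedigree(cfg)
  A <- build_numerator_relationship(ped)
  ids <- ped$animal_id
  eA <- eigen(A, symmetric = TRUE)
  cA <- chol(A + diag(1e-10, nrow(A)))
  ests <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    classes <- setNames(sample(c("GG", "AG", "AA"), nrow(ped), TRUE,
                               c(.75, .22, .03)), ids)
    phen <- simulate_phenotypes(ped, A, classes, cfg, effect = c(AG = 1.6, AA = 0),
                                chol_A = cA, seed = 2000 + s)
    fit <- reml_fit(setNames(phen$value, ids), classes, A, eigen_A = eA)
    unname(fit$beta["AG-GG"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1.6), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("genotype_contrasts stars use the two conventional thresholds", {
  fake <- structure(list(
    mu = 0, beta = c(`AG-GG` = 1, `AA-GG` = 2), se = c(`AG-GG` = 0.3, `AA-GG` = 1.5),
    p_value = c(`AG-GG` = 0.0008, `AA-GG` = 0.18), sigma_a2 = 1, sigma_e2 = 1,
    lambda = 1, u = numeric(0), loglik = 0, profile_fn = NULL, n = 10,
    non_estimable = character(0)), class = "mixed_model_fit")
  ct <- genotype_contrasts(fake, n_tests = 8)
  expect_equal(ct$stars, c("**", ""))
  expect_equal(ct$p_bonferroni, pmin(1, c(0.0008, 0.18) * 8))
})
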