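test_that("degenerate model: sigma_a2 = 0, no effect -> variance ~ sigma_e2", {
  ped <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 5,
                                      n_offspring_per_gen = 745, seed = 2))
  cfg <- sim_config(phenotype_sigma_a2 = 0, phenotype_sigma_e2 = 25, seed = 2)
  A <- diag(nrow(ped)); dimnames(A) <- list(ped$animal_id, ped$animal_id)
  classes <- setNames(rep("GG", nrow(ped)), ped$animal_id)
  phen <- simulate_phenotypes(ped, A, classes, cfg, mu = 50, effect = c(AG = 0, AA = 0))
  n <- nrow(phen)
  expect_gt(n, 2900)
  # chi-square sampling bounds for the variance at this n
  expect_lt(abs(var(phen$value) - 25), 4 * 25 * sqrt(2 / n))
  expect_equal(mean(phen$value), 50, tolerance = 4 * 5 / sqrt(n))
})

test_that("planted heterozygote contrast shows up in raw class means", {
  cfg <- sim_config(n_founders = 12, n_generations = 4, n_offspring_per_gen = 300,
                    phenotype_sigma_a2 = 0.3 * 9.4^2,
                    phenotype_sigma_e2 = 0.7 * 9.4^2, seed = 6)
  ped <- simulate_pedigree(cfg)
  A <- build_numerator_relationship(ped)
  diffs <- vapply(1:12, function(s) {
    set.seed(500 + s)
    classes <- setNames(sample(c("GG", "AG"), nrow(ped), TRUE, c(.85, .15)),
                        ped$animal_id)
    phen <- simulate_phenotypes(ped, A, classes, cfg, mu = 63,
                                effect = c(AG = 1.6, AA = 0), seed = 600 + s)
    means <- tapply(phen$value, phen$genotype, mean)
    unname(means["AG"] - means["GG"])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 1.6), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("polygenic draws have covariance A * sigma_a2 (Monte-Carlo oracle)", {
  ped <- toy_pedigree()
  ped <- rbind(ped, data.frame(animal_id = c("Y1", "Y2", "Y3"),
                               sire_id = c("X1", "X1", "X2"),
                               dam_id = c("C2", "C2", "C2"),
                               sex = "F", birth_cohort = 4L))
  A <- build_numerator_relationship(ped)
  cfg <- sim_config(phenotype_sigma_a2 = 4, phenotype_sigma_e2 = 1, seed = 1)
  classes <- setNames(rep("GG", nrow(ped)), ped$animal_id)
  cA <- chol(A + diag(1e-10, nrow(A)))
  U <- vapply(1:2000, function(s) {
    phen <- simulate_phenotypes(ped, A, classes, cfg, mu = 0,
                                effect = c(AG = 0, AA = 0), chol_A = cA, seed = s)
    attr(phen, "components")$u
  }, numeric(nrow(ped)))
  emp <- cov(t(U))
  want <- 4 * A
  # Monte-Carlo tolerance: sampling SE of a covariance entry ~ (v_ii v_jj + v_ij^2)^.5/sqrt(R)
  tol <- 3 * sqrt(outer(diag(want), diag(want)) + want^2) / sqrt(2000)
  expect_true(all(abs(emp - want) <= tol + 0.02))
})

test_that("dimension errors are raised for non-conformable inputs", {
  ped <- toy_pedigree()
  A <- build_numerator_relationship(ped)[1:3, 1:3]
  cfg <- sim_config(seed = 1)
  classes <- setNames(rep("GG", nrow(ped)), ped$animal_id)
  expect_error(simulate_phenotypes(ped, A, classes, cfg), "dimension error")
})

test_that("log-normal moment matching agrees with a quadrature oracle", {
  for (spec in list(c(3.9, 0.6), c(16, 0.8), c(2.1, 0.7), c(10, 6))) {
    lp <- lognormal_params(spec[1], spec[2])
    m <- integrate(function(x) x * dlnorm(x, lp$meanlog, lp$sdlog), 0, Inf,
                   rel.tol = 1e-10)$value
    m2 <- integrate(function(x) x^2 * dlnorm(x, lp$meanlog, lp$sdlog), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(m, spec[1], tolerance = 1e-6)
    expect_equal(sqrt(m2 - m^2), spec[2], tolerance = 1e-6)
  }
  expect_error(lognormal_params(-1, 2), "positive")
})

test_that("paranodal simulator hits group targets and handles n = 1", {
  para <- simulate_paranodal_lengths(seed = 3)
  expect_true(all(para$length_um > 0))
  s <- summarize_groups(para)
  targets <- c(affected_in_lesion = 16, affected_out_lesion = 2.1, control_wt = 3.9)
  for (g in names(targets)) {
    row <- s[s$group == g, ]
    expect_lt(abs(row$mean - targets[[g]]), 3 * row$se + 1e-9)
  }
  tiny <- simulate_paranodal_lengths(data.frame(
    group = c("a", "b", "c"), mean = c(1, 2, 3), sd = c(0.1, 0.2, 0.3),
    n = c(1L, 1L, 1L)), seed = 1)
  expect_equal(nrow(tiny), 3L)
  expect_error(simulate_paranodal_lengths(data.frame(
    group = "a", mean = 0, sd = 1, n = 5L), seed = 1), "configuration error")
})

test_that("same seed, same data across all simulators", {
  expect_identical(simulate_paranodal_lengths(seed = 9),
                   simulate_paranodal_lengths(seed = 9))
  cfg <- sim_config(seed = 10)
  ped <- simulate_pedigree(sim_config(n_founders = 6, n_generations = 3,
                                      n_offspring_per_gen = 30, seed = 10))
  A <- build_numerator_relationship(ped)
  classes <- setNames(rep("GG", nrow(ped)), ped$animal_id)
  expect_identical(simulate_phenotypes(ped, A, classes, cfg)$value,
                   simulate_phenotypes(ped, A, classes, cfg)$value)
  expect_identical(simulate_variant_table(config = cfg)$variants,
                   simulate_variant_table(config = cfg)$variants)
})
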