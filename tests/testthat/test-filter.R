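test_that("cascade reproduces truth bookkeeping exactly", {
  cfg <- sim_config(seed = 14)
  vt <- simulate_variant_table(config = cfg)
  res <- apply_filter_cascade(vt$variants, vt$case_ids, vt$control_ids,
                              cfg$causal_interval)
  cc <- vt$category_counts
  expect_equal(res$report$n_in[1], sum(cc))
  expect_equal(res$report$n_out[1], sum(cc) - cc[["outside_interval"]])
  expect_equal(res$report$n_out[2], res$report$n_out[1] - cc[["fails_genotype"]])
  expect_equal(res$report$n_out[3], res$report$n_out[2] - cc[["known_in_catalogue"]])
  expect_equal(res$report$n_out[4], res$report$n_out[3] - cc[["on_array"]])
  expect_equal(res$report$n_out[5], 1L)
  expect_equal(res$survivors$variant_id, vt$causal_id)
  # every dropped variant is attributed to its first failing step
  expect_equal(length(res$failed_step), sum(cc) - 1L)
  attributed <- table(factor(res$failed_step,
                             levels = c("in_interval", "segregation",
                                        "not_in_catalogue", "not_on_array",
                                        "protein_altering")))
  expect_equal(unname(attributed[["in_interval"]]), cc[["outside_interval"]])
  expect_equal(unname(attributed[["segregation"]]), cc[["fails_genotype"]])
  expect_equal(unname(attributed[["protein_altering"]]), cc[["not_protein_altering"]])
})

test_that("default counts reproduce the published cascade shape", {
  cfg <- sim_config(seed = 20)
  vt <- simulate_variant_table(config = cfg)
  res <- apply_filter_cascade(vt$variants, vt$case_ids, vt$control_ids,
                              cfg$causal_interval)
  expect_equal(res$report$step,
               c("in_interval", "segregation", "not_in_catalogue",
                 "not_on_array", "protein_altering"))
  expect_equal(res$report$n_out, c(1503L, 367L, 159L, 146L, 1L))
  # counts are monotone non-increasing and survivors are a subset
  expect_true(all(diff(res$report$n_out) <= 0))
  expect_true(all(res$survivors$variant_id %in% vt$variants$variant_id))
})

test_that("causal-only table survives every step; empty input yields zero counts", {
  cfg <- sim_config(n_background_outside = 0L, n_background_genotype = 0L,
                    n_background_known = 0L, n_background_array = 0L,
                    n_background_nonprotein = 0L, seed = 4)
  vt <- simulate_variant_table(config = cfg)
  expect_equal(nrow(vt$variants), 1L)
  res <- apply_filter_cascade(vt$variants, vt$case_ids, vt$control_ids,
                              cfg$causal_interval)
  expect_equal(res$report$n_out, rep(1L, 5L))
  empty <- vt$variants[0, ]
  res0 <- apply_filter_cascade(empty, vt$case_ids, vt$control_ids,
                               cfg$causal_interval)
  expect_equal(res0$report$n_out, rep(0L, 5L))
  expect_error(apply_filter_cascade(vt$variants, character(0), vt$control_ids,
                                    cfg$causal_interval), "empty case")
})

test_that("missing case calls fail segregation; control modes differ", {
  cfg <- sim_config(seed = 2)
  vt <- simulate_variant_table(config = cfg, n_controls = 2L)
  v <- vt$variants[vt$variants$category == "causal", ]
  v[[vt$case_ids[1]]] <- "missing"
  res <- apply_filter_cascade(v, vt$case_ids, vt$control_ids, cfg$causal_interval)
  expect_equal(res$report$n_out[2], 0L)
  # one hom_alt control kills under "all" but survives under "any"
  v2 <- vt$variants[vt$variants$category == "causal", ]
  v2[[vt$control_ids[1]]] <- "hom_alt"
  all_mode <- apply_filter_cascade(v2, vt$case_ids, vt$control_ids,
                                   cfg$causal_interval, control_mode = "all")
  any_mode <- apply_filter_cascade(v2, vt$case_ids, vt$control_ids,
                                   cfg$causal_interval, control_mode = "any")
  expect_equal(all_mode$report$n_out[2], 0L)
  expect_equal(any_mode$report$n_out[2], 1L)
})

test_that("annotation route classifies the planted variant at the toy locus", {
  m <- toy_ataxia_model()
  v <- data.frame(chrom = m$variant$chrom, pos = m$variant$pos,
                  ref = m$variant$ref, alt = m$variant$alt,
                  case1 = "hom_alt", case2 = "hom_alt", ctrl = "het",
                  known_in_catalogue = FALSE, on_array_other_breeds = FALSE,
                  stringsAsFactors = FALSE)
  iv <- genomic_interval("chr19", 26848700, 27529700)
  res <- apply_filter_cascade(v, c("case1", "case2"), "ctrl", iv,
                              transcripts = list(m$transcript), genome = m$genome)
  expect_equal(nrow(res$survivors), 1L)
})

test_that("synonymous splice-region rescue requires the flag and the score drop", {
  iv <- genomic_interval("chr19", 26848700, 27529700)
  v <- data.frame(chrom = "chr19", pos = 27041000, ref = "G", alt = "A",
                  case1 = "hom_alt", ctrl = "hom_ref",
                  known_in_catalogue = FALSE, on_array_other_breeds = FALSE,
                  consequence = "synonymous+splice_region",
                  donor_delta = -3.3, stringsAsFactors = FALSE)
  off <- apply_filter_cascade(v, "case1", "ctrl", iv)
  expect_equal(nrow(off$survivors), 0L)
  on <- apply_filter_cascade(v, "case1", "ctrl", iv, keep_splice_synonymous = TRUE)
  expect_equal(nrow(on$survivors), 1L)
  weak <- v; weak$donor_delta <- -0.2
  expect_equal(nrow(apply_filter_cascade(weak, "case1", "ctrl", iv,
                                         keep_splice_synonymous = TRUE)$survivors), 0L)
})
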