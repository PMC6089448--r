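make_gm <- function(codes, spacing = 1e5) {
  # single-chromosome genotype matrix from a list of per-sample code vectors
  n <- length(codes[[1]])
  map <- data.frame(marker_id = sprintf("m%03d", 1:n), chrom = "chr1",
                    pos_bp = spacing * (1:n), pos_cm = spacing * (1:n) / 1e6)
  g <- do.call(rbind, codes)
  storage.mode(g) <- "integer"
  rownames(g) <- names(codes)
  genotype_matrix(g, map)
}

test_that("degenerate samples: all-het gives nothing, saturated gives one run", {
  p <- roh_params(min_markers = 5, min_length_bp = 0)
  gm <- make_gm(list(het = rep(1L, 100), hom = rep(2L, 100)))
  expect_equal(nrow(detect_roh(gm, "het", p)), 0L)
  sat <- detect_roh(gm, "hom", p)
  expect_equal(nrow(sat), 1L)
  expect_equal(sat$n_markers, 100L)
  expect_equal(sat$start_bp, 1e5)
  expect_equal(sat$end_bp, 1e7)
})

test_that("unknown sample and unsorted markers raise errors", {
  gm <- make_gm(list(a = rep(0L, 10)))
  expect_error(detect_roh(gm, "zz"), "unknown sample")
  map <- gm$map; map$pos_bp[2] <- 0
  expect_error(genotype_matrix(gm$geno, map), "strictly increasing")
})

test_that("detected segments equal exhaustive enumeration on random toys", {
  p <- roh_params(min_markers = 8, min_length_bp = 3e5, max_het_calls = 1,
                  max_missing_calls = 2)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(40:120, 1)
    codes <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                    prob = c(0.42, 0.12, 0.42, 0.04))
    gm <- make_gm(list(s = codes), spacing = 5e4)
    got <- detect_roh(gm, "s", p)
    want <- oracle_roh(codes, gm$map$pos_bp, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start_idx, want$start_idx)
      expect_equal(got$end_idx, want$end_idx)
    }
  }
})

test_that("opposite-allele homozygosity is rejected when a shared allele is required", {
  p <- roh_params(min_markers = 5, min_length_bp = 0, min_case_fraction = 1)
  gm <- make_gm(list(a = rep(0L, 30), b = rep(2L, 30)))
  res <- map_shared_interval(gm, c("a", "b"), p)
  expect_equal(nrow(res$intervals), 0L)
  expect_match(res$diagnostics, "no interval")
  # same-allele homozygosity is accepted
  gm2 <- make_gm(list(a = rep(2L, 30), b = rep(2L, 30)))
  res2 <- map_shared_interval(gm2, c("a", "b"), p)
  expect_equal(nrow(res2$intervals), 1L)
  expect_true(res2$intervals$shared_allele_consistent[1])
})

test_that("phenocopy tolerance: lowering min_case_fraction never loses intervals", {
  set.seed(3)
  base <- rep(2L, 60)
  mk_case <- function() { x <- base; x[sample(60, 3)] <- 1L; x }
  samples <- c(lapply(1:6, function(i) base), list(odd = sample(c(0L, 1L), 60, TRUE)))
  names(samples) <- c(sprintf("c%d", 1:6), "odd")
  gm <- make_gm(samples)
  p_hi <- roh_params(min_markers = 10, min_length_bp = 0, min_case_fraction = 1)
  p_lo <- roh_params(min_markers = 10, min_length_bp = 0, min_case_fraction = 0.8)
  hi <- map_shared_interval(gm, names(samples), p_hi)$intervals
  lo <- map_shared_interval(gm, names(samples), p_lo)$intervals
  expect_gte(nrow(lo), nrow(hi))
  expect_equal(nrow(hi), 0L) # the odd sample blocks full sharing
  expect_equal(nrow(lo), 1L)
  expect_match(lo$discordant[1], "odd")
})

test_that("the minimal shared interval is contained in every supporting segment", {
  cfg <- small_sim_config(seed = 11)
  gd <- gene_drop(simulate_pedigree(cfg), marker_map(cfg), cfg)
  cases <- gd$truth$cases$animal_id
  res <- map_shared_interval(gd$genotypes, cases, roh_params())
  expect_gt(nrow(res$intervals), 0L)
  top <- res$intervals[1, ]
  sup <- strsplit(top$supporting, ",")[[1]]
  for (s in sup) {
    segs <- detect_roh(gd$genotypes, s, roh_params())
    segs <- segs[segs$chrom == top$chrom, ]
    expect_true(any(segs$start_bp <= top$start_bp & segs$end_bp >= top$end_bp))
  }
  # supporting + discordant partition the case set
  dis <- strsplit(top$discordant, ",")[[1]]
  expect_setequal(c(sup, dis), cases)
})
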