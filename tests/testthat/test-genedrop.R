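test_that("no recombination: all AA cases share the founder haplotype end to end", {
  cfg <- small_sim_config(seed = 2, cm_per_mb = 1e-9, genotype_error = 0,
                          missing_rate = 0, n_cases_aa = 10L, n_phenocopies = 0L)
  ped <- simulate_pedigree(cfg)
  map <- marker_map(cfg)
  gd <- gene_drop(ped, map, cfg, keep_haplotypes = TRUE)
  H <- gd$haplotypes
  founder_row <- match(gd$truth$disease_founder, gd$truth$pedigree$animal_id)
  disease_hap <- H$paternal[founder_row, ]
  aa <- names(gd$truth$carrier_status)[gd$truth$carrier_status == "AA"]
  sel <- H$loci$chrom == cfg$causal_interval$chrom &
    H$loci$pos_bp >= cfg$causal_interval$start &
    H$loci$pos_bp <= cfg$causal_interval$end
  for (a in aa) {
    r <- match(a, gd$truth$pedigree$animal_id)
    expect_equal(H$paternal[r, sel], disease_hap[sel])
    expect_equal(H$maternal[r, sel], disease_hap[sel])
  }
})

test_that("case ascertainment records the configured AA and phenocopy design", {
  cfg <- small_sim_config(seed = 3)
  gd <- gene_drop(simulate_pedigree(cfg), marker_map(cfg), cfg)
  cases <- gd$truth$cases
  expect_equal(nrow(cases), 46L)
  expect_equal(sum(cases$phenocopy), 5L)
  st <- gd$truth$carrier_status[cases$animal_id]
  expect_true(all(st[!cases$phenocopy] == "AA"))
  expect_true(all(st[cases$phenocopy] != "AA"))
  # only AA non-phenocopy animals are labelled affected
  expect_equal(sum(!cases$phenocopy), 41L)
})

test_that("gene drop is deterministic given the seed", {
  cfg <- small_sim_config(seed = 5, markers_per_chrom = 60L, n_chromosomes = 2L,
                          causal_interval = genomic_interval("chr1", 26848700, 27529700))
  ped <- simulate_pedigree(cfg)
  map <- marker_map(cfg)
  g1 <- gene_drop(ped, map, cfg)
  g2 <- gene_drop(ped, map, cfg)
  expect_identical(g1$genotypes$geno, g2$genotypes$geno)
  expect_identical(g1$truth$cases, g2$truth$cases)
})

test_that("Mendelian consistency holds for raw haplotypes", {
  cfg <- sim_config(n_founders = 8, n_generations = 3, n_offspring_per_gen = 60,
                    n_chromosomes = 2, markers_per_chrom = 80,
                    chrom_length_bp = 5e7,
                    causal_interval = genomic_interval("chr1", 26848700, 27529700),
                    n_cases_aa = 0L, n_phenocopies = 0L, seed = 9)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, marker_map(cfg), cfg, keep_haplotypes = TRUE)
  H <- gd$haplotypes
  idx <- setNames(seq_len(nrow(ped)), ped$animal_id)
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire_id[i]
    if (!is.na(s)) {
      si <- idx[[s]]
      ok <- H$paternal[i, ] == H$paternal[si, ] | H$paternal[i, ] == H$maternal[si, ]
      expect_true(all(ok))
    }
    d <- ped$dam_id[i]
    if (!is.na(d)) {
      di <- idx[[d]]
      ok <- H$maternal[i, ] == H$paternal[di, ] | H$maternal[i, ] == H$maternal[di, ]
      expect_true(all(ok))
    }
  }
  # raw genotypes equal haplotype sums at the marker loci
  mcols <- which(H$loci$marker_id != ".causal")
  expect_equal(unname(gd$geno_raw),
               unname(H$paternal[, mcols] + H$maternal[, mcols]))
})

test_that("transmission is unbiased: offspring frequency matches parents (binomial oracle)", {
  # 100 full-sib offspring x 100 drops = 10,000 transmissions per parent pair
  ped <- data.frame(
    animal_id = c("s", "d", sprintf("o%03d", 1:100)),
    sire_id = c(NA, NA, rep("s", 100)),
    dam_id = c(NA, NA, rep("d", 100)),
    sex = c("M", "F", rep("M", 100)),
    birth_cohort = c(0L, 0L, rep(1L, 100)))
  attr(ped, "predominant_founder") <- "s"
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_chromosomes = 1,
                    markers_per_chrom = 40, chrom_length_bp = 5e7,
                    causal_interval = genomic_interval("chr1", 26848700, 27529700),
                    genotype_error = 0, missing_rate = 0,
                    n_cases_aa = 0L, n_phenocopies = 0L, seed = 1)
  map <- marker_map(cfg)
  tot <- matrix(0, 100, nrow(map))
  par_freq <- NULL
  for (r in 1:100) {
    cfg$seed <- r
    gd <- gene_drop(ped, map, cfg, keep_haplotypes = TRUE)
    off <- gd$genotypes$geno[3:102, ]
    tot <- tot + off
    pf <- (gd$genotypes$geno["s", ] + gd$genotypes$geno["d", ]) / 4
    par_freq <- rbind(par_freq, pf)
  }
  # offspring allele frequency per marker vs average parental frequency:
  # 10,000 Bernoulli(p) pairs per marker
  obs <- colSums(tot) / (2 * 100 * 100)
  expe <- colMeans(par_freq)
  se <- sqrt(pmax(expe * (1 - expe), 1e-6) / (2 * 100 * 100))
  expect_true(all(abs(obs - expe) <= 3.5 * se + 0.25 / 20000))
})

test_that("marker map problems raise input errors", {
  cfg <- small_sim_config(seed = 1)
  ped <- simulate_pedigree(sim_config(n_founders = 4, n_generations = 2,
                                      n_offspring_per_gen = 10, seed = 1))
  map <- marker_map(cfg)
  bad <- map
  bad$pos_bp[2] <- bad$pos_bp[1] # duplicate within chromosome
  expect_error(gene_drop(ped, bad, cfg), "input error")
})
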