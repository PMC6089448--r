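# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: path enumeration instead of dynamic programming,
# exhaustive window search instead of the two-pointer scan, whole-sequence
# translation instead of codon lookup, permutation instead of the Levene
# formula, Monte-Carlo gene dropping instead of the tabular method.

# expected founder contribution by explicit ancestor-path counting:
# sum over all distinct ancestor paths from `id` up to `founder` of (1/2)^L
oracle_contribution <- function(ped, id, founder) {
  sire <- setNames(ped$sire_id, ped$animal_id)
  dam <- setNames(ped$dam_id, ped$animal_id)
  rec <- function(a, depth) {
    if (a == founder) return(2^-depth)
    tot <- 0
    if (!is.na(sire[[a]])) tot <- tot + rec(sire[[a]], depth + 1)
    if (!is.na(dam[[a]])) tot <- tot + rec(dam[[a]], depth + 1)
    tot
  }
  rec(id, 0)
}

# exhaustive enumeration of maximal qualifying homozygosity windows
oracle_roh <- function(codes, pos, params) {
  n <- length(codes)
  het <- !is.na(codes) & codes == 1L
  mis <- is.na(codes)
  hom <- !het & !mis
  qual <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!hom[i]) next
    for (j in i:n) {
      if (!hom[j]) next
      win <- i:j
      qual[i, j] <- sum(het[win]) <= params$max_het_calls &&
        sum(mis[win]) <= params$max_missing_calls
    }
  }
  segs <- which(qual, arr.ind = TRUE)
  if (!nrow(segs)) return(NULL)
  # maximal: no strictly containing qualifying window
  keep <- vapply(seq_len(nrow(segs)), function(r) {
    i <- segs[r, 1]; j <- segs[r, 2]
    for (i2 in 1:i) for (j2 in j:n) {
      if ((i2 < i || j2 > j) && qual[i2, j2]) return(FALSE)
    }
    TRUE
  }, logical(1))
  segs <- segs[keep, , drop = FALSE]
  ok <- (segs[, 2] - segs[, 1] + 1L) >= params$min_markers &
    (pos[segs[, 2]] - pos[segs[, 1]]) >= params$min_length_bp
  segs <- segs[ok, , drop = FALSE]
  if (!nrow(segs)) return(NULL)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  data.frame(start_idx = unname(segs[, 1]), end_idx = unname(segs[, 2]))
}

# classify a single-base CDS substitution by translating the whole mutated
# CDS with Biostrings and diffing the protein sequences
oracle_classify_substitution <- function(cds, i, alt_base) {
  mut <- cds
  substr(mut, i, i) <- alt_base
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                               no.init.codon = TRUE))
  k <- (i - 1) %/% 3 + 1
  r <- substr(aa_ref, k, k); a <- substr(aa_alt, k, k)
  if (r == a) "synonymous"
  else if (a == "*") "stop_gain"
  else if (r == "*") "stop_loss"
  else if (k == 1 && r == "M") "start_loss"
  else "missense"
}

# Monte-Carlo permutation estimate of the one-sided homozygote-deficit
# p-value conditional on allele counts
oracle_hwe_deficit_mc <- function(n_GG, n_AG, n_AA, reps = 20000, seed = 1) {
  n <- n_GG + n_AG + n_AA
  nA <- 2 * n_AA + n_AG
  alleles <- c(rep(1L, nA), rep(0L, 2L * n - nA))
  set.seed(seed)
  aa <- replicate(reps, {
    perm <- sample(alleles)
    sum(perm[seq(1, 2 * n, 2)] + perm[seq(2, 2 * n, 2)] == 2L)
  })
  mean(aa <= n_AA)
}

# Monte-Carlo gene-dropping estimate of pairwise additive relationship:
# drop unique founder alleles, A_ij = E[shared] (i.e. 2 * kinship)
mc_relationship <- function(ped, ndrops, seed = 1) {
  set.seed(seed)
  id <- ped$animal_id
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  ord <- pedigree_order(ped)
  sire <- idx[as.character(ped$sire_id)]
  dam <- idx[as.character(ped$dam_id)]
  a1 <- matrix(0L, n, ndrops)
  a2 <- matrix(0L, n, ndrops)
  allele_counter <- 0L
  for (i in ord) {
    if (is.na(sire[i])) {
      allele_counter <- allele_counter + 1L
      a1[i, ] <- allele_counter
    } else {
      pick <- runif(ndrops) < 0.5
      a1[i, ] <- ifelse(pick, a1[sire[i], ], a2[sire[i], ])
    }
    if (is.na(dam[i])) {
      allele_counter <- allele_counter + 1L
      a2[i, ] <- allele_counter
    } else {
      pick <- runif(ndrops) < 0.5
      a2[i, ] <- ifelse(pick, a1[dam[i], ], a2[dam[i], ])
    }
  }
  est <- matrix(0, n, n, dimnames = list(id, id))
  se <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        x <- 1 + (a1[i, ] == a2[i, ])
      } else {
        x <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 2
      }
      est[i, j] <- est[j, i] <- mean(x)
      se[i, j] <- se[j, i] <- stats::sd(x) / sqrt(ndrops)
    }
  }
  list(est = est, se = se)
}

# a small fixed linebred pedigree used by several tests
toy_pedigree <- function() {
  data.frame(
    animal_id = c("S1", "D1", "D2", "C1", "C2", "X1", "X2"),
    sire_id = c(NA, NA, NA, "S1", "S1", "C1", "X1"),
    dam_id = c(NA, NA, NA, "D1", "D2", "C2", "C2"),
    sex = c("M", "F", "F", "M", "F", "M", "M"),
    birth_cohort = c(0L, 0L, 0L, 1L, 1L, 2L, 3L),
    stringsAsFactors = FALSE)
}

# compact simulation config used by recovery-style tests (scaled-down map)
small_sim_config <- function(seed, ...) {
  args <- list(n_founders = 12L, n_generations = 9L, n_offspring_per_gen = 150L,
               n_chromosomes = 4L, chrom_length_bp = 3e7, markers_per_chrom = 600L,
               causal_interval = genomic_interval("chr2", 26848700, 27529700),
               causal_position = 27041449, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
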