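#' Genotype matrix container
#'
#' Samples x markers matrix of alternate-allele counts in {0, 1, 2, NA},
#' plus the marker map. Marker positions must be strictly increasing within
#' each chromosome.
#'
#' @param geno integer matrix (samples x markers, NA = missing call).
#' @param map `data.frame` with `marker_id`, `chrom`, `pos_bp`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map) {
  stopifnot(is.matrix(geno), all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
  if (ncol(geno) != nrow(map)) stop("geno columns must match map rows", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("input error: marker positions not strictly increasing on %s", ch),
           call. = FALSE)
    }
  }
  colnames(geno) <- map$marker_id
  structure(list(geno = geno, map = map, samples = rownames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

# One meiosis: recombine a parent's two haplotype vectors into a gamete.
# Crossovers are a Poisson process on the genetic map (pos_cm), independent
# per chromosome; `chrom_index` groups loci, `len_cm` gives map lengths.
recombine_gamete <- function(h1, h2, pos_cm, chrom_starts, chrom_ends, len_cm) {
  out <- integer(length(h1))
  for (ci in seq_along(chrom_starts)) {
    sel <- chrom_starts[ci]:chrom_ends[ci]
    k <- rpois(1L, len_cm[ci] / 100)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      out[sel] <- if (start == 0L) h1[sel] else h2[sel]
    } else {
      bp <- sort(runif(k, 0, len_cm[ci]))
      src <- (start + findInterval(pos_cm[sel], bp)) %% 2L
      out[sel] <- ifelse(src == 0L, h1[sel], h2[sel])
    }
  }
  out
}

#' Gene-drop simulation of genotypes down a pedigree
#'
#' Assigns founder haplotypes (independent per-marker alternate-allele
#' frequencies drawn from `config$founder_freq_range`), plants the disease
#' haplotype on one chromosome of the designated founder (causal allele at
#' `config$causal_position`), and transmits one recombined haplotype per
#' parent to every non-founder (crossovers as a Poisson process on the
#' genetic map). Animals homozygous for the planted allele are homozygous by
#' descent across the causal interval except where recombination has
#' shortened the shared segment.
#'
#' Case ascertainment mirrors how cases of a rare recessive reach a national
#' observatory: naturally arising homozygotes are supplemented with offspring
#' of carrier x carrier matings sampled from the pedigree until
#' `config$n_cases_aa` homozygous cases exist; `config$n_phenocopies`
#' unaffected-genotype animals are then labelled as phenocopy cases.
#'
#' The genotype error layer (symmetric per-allele miscall at
#' `config$genotype_error`, then missingness at `config$missing_rate`) is
#' applied last, so Mendelian consistency holds for the raw haplotypes.
#'
#' @param ped pedigree from [simulate_pedigree()] (or compatible).
#' @param map marker map from [marker_map()] (sorted, no duplicate positions).
#' @param config a [sim_config()].
#' @param keep_haplotypes also return per-animal transmitted haplotypes and
#'   the pre-error genotype matrix (memory-heavy; for validation).
#' @return list with `genotypes` (a [genotype_matrix()], error layer applied)
#'   and `truth` (class `sim_truth`: causal interval/position, per-animal
#'   carrier status, case table with phenocopy flags, disease founder).
#' @export
gene_drop <- function(ped, map, config, keep_haplotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ped <- validate_pedigree(ped)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("input error: marker map unsorted or duplicated on %s", ch),
           call. = FALSE)
    }
  }
  civ <- config$causal_interval
  # insert the causal locus as a pseudo-marker for transmission
  loci <- rbind(map[, c("marker_id", "chrom", "pos_bp", "pos_cm")],
                data.frame(marker_id = ".causal", chrom = civ$chrom,
                           pos_bp = config$causal_position,
                           pos_cm = config$causal_position / 1e6 * config$cm_per_mb))
  loci <- loci[order(match(loci$chrom, unique(loci$chrom)), loci$pos_bp), ]
  if (anyDuplicated(loci[, c("chrom", "pos_bp")])) {
    stop("input error: duplicate marker position (or marker at causal position)",
         call. = FALSE)
  }
  causal_idx <- which(loci$marker_id == ".causal")
  nl <- nrow(loci)
  chroms <- unique(loci$chrom)
  chrom_starts <- match(chroms, loci$chrom)
  chrom_ends <- c(chrom_starts[-1L] - 1L, nl)
  len_cm <- vapply(seq_along(chroms), function(ci) {
    max(loci$pos_cm[chrom_starts[ci]:chrom_ends[ci]])
  }, numeric(1))

  id <- ped$animal_id
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  ord <- pedigree_order(ped)
  founder <- is.na(ped$sire_id) & is.na(ped$dam_id)
  disease_founder <- attr(ped, "predominant_founder") %||% id[founder][1L]

  res <- with_seed(config$seed + 1L, {
    freq <- runif(nl, config$founder_freq_range[1], config$founder_freq_range[2])
    freq[causal_idx] <- 0 # planted allele has a single origin
    H1 <- matrix(0L, n, nl) # paternal gamete
    H2 <- matrix(0L, n, nl) # maternal gamete
    draw_founder_hap <- function() as.integer(runif(nl) < freq)
    for (i in which(founder)) {
      H1[i, ] <- draw_founder_hap()
      H2[i, ] <- draw_founder_hap()
    }
    H1[idx[disease_founder], causal_idx] <- 1L
    for (i in ord) {
      if (founder[i]) next
      s <- idx[ped$sire_id[i]]
      H1[i, ] <- if (!is.na(s)) {
        recombine_gamete(H1[s, ], H2[s, ], loci$pos_cm, chrom_starts, chrom_ends, len_cm)
      } else draw_founder_hap()
      d <- idx[ped$dam_id[i]]
      H2[i, ] <- if (!is.na(d)) {
        recombine_gamete(H1[d, ], H2[d, ], loci$pos_cm, chrom_starts, chrom_ends, len_cm)
      } else draw_founder_hap()
    }

    ped2 <- ped
    status <- c("GG", "AG", "AA")[H1[, causal_idx] + H2[, causal_idx] + 1L]
    names(status) <- ped2$animal_id

    # ascertain carrier x carrier case families until enough AA cases exist
    n_aa_needed <- config$n_cases_aa - sum(status == "AA")
    if (n_aa_needed > 0L) {
      carriers_m <- ped2$animal_id[status[ped2$animal_id] == "AG" & ped2$sex == "M"]
      carriers_f <- ped2$animal_id[status[ped2$animal_id] == "AG" & ped2$sex == "F"]
      if (!length(carriers_m) || !length(carriers_f)) {
        stop("input error: no carrier x carrier mating available for case ascertainment",
             call. = FALSE)
      }
      cohort <- max(ped2$birth_cohort) + 1L
      extra <- 0L
      attempts <- 0L
      max_attempts <- 1000L * config$n_cases_aa
      while (n_aa_needed > 0L && attempts < max_attempts) {
        attempts <- attempts + 1L
        s <- sample(carriers_m, 1L); d <- sample(carriers_f, 1L)
        g1 <- recombine_gamete(H1[idx[s], ], H2[idx[s], ], loci$pos_cm,
                               chrom_starts, chrom_ends, len_cm)
        g2 <- recombine_gamete(H1[idx[d], ], H2[idx[d], ], loci$pos_cm,
                               chrom_starts, chrom_ends, len_cm)
        if (g1[causal_idx] + g2[causal_idx] == 2L) {
          extra <- extra + 1L
          aid <- sprintf("CASE%03d", extra)
          ped2 <- rbind(ped2, data.frame(animal_id = aid, sire_id = s, dam_id = d,
                                         sex = sample(c("M", "F"), 1L),
                                         birth_cohort = cohort,
                                         stringsAsFactors = FALSE))
          H1 <- rbind(H1, g1); H2 <- rbind(H2, g2)
          idx <- c(idx, setNames(nrow(H1), aid))
          status <- c(status, setNames("AA", aid))
          n_aa_needed <- n_aa_needed - 1L
        }
      }
      if (n_aa_needed > 0L) {
        stop("input error: case ascertainment failed to reach the configured AA count",
             call. = FALSE)
      }
    }

    aa_ids <- names(status)[status == "AA"]
    aa_cases <- if (length(aa_ids) > config$n_cases_aa) {
      sample(aa_ids, config$n_cases_aa)
    } else aa_ids
    # phenocopies emulate cases that do not bear the mapped homozygous
    # haplotype: exclude animals homozygous and state-identical to the
    # disease founder haplotype over any 6+ consecutive loci on the causal
    # chromosome (the shortest tract the interval mapper could mistake for
    # haplotype sharing)
    chrom_sel <- which(loci$chrom == civ$chrom)
    fhap <- H1[idx[disease_founder], chrom_sel]
    carries_tract <- vapply(seq_len(nrow(H1)), function(r) {
      shared <- H1[r, chrom_sel] == fhap & H2[r, chrom_sel] == fhap
      r1 <- rle(shared)
      any(r1$values & r1$lengths >= 6L)
    }, logical(1))
    pool <- setdiff(names(status)[status != "AA" & !carries_tract], aa_cases)
    pheno_ids <- if (config$n_phenocopies > 0L) {
      sample(pool, config$n_phenocopies)
    } else character(0)
    cases <- data.frame(animal_id = c(aa_cases, pheno_ids),
                        phenocopy = c(rep(FALSE, length(aa_cases)),
                                      rep(TRUE, length(pheno_ids))),
                        stringsAsFactors = FALSE)

    marker_cols <- which(loci$marker_id != ".causal")
    raw <- H1[, marker_cols, drop = FALSE] + H2[, marker_cols, drop = FALSE]
    rownames(raw) <- ped2$animal_id

    # error layer: symmetric per-allele miscall, then missingness
    eps <- config$genotype_error
    g <- raw
    if (eps > 0) {
      f1 <- matrix(runif(length(g)) < eps, nrow(g))
      f2 <- matrix(runif(length(g)) < eps, nrow(g))
      a1 <- H1[, marker_cols, drop = FALSE]; a2 <- H2[, marker_cols, drop = FALSE]
      g <- abs(a1 - f1) + abs(a2 - f2)
      storage.mode(g) <- "integer"
      rownames(g) <- ped2$animal_id
    }
    if (config$missing_rate > 0) {
      g[matrix(runif(length(g)) < config$missing_rate, nrow(g))] <- NA_integer_
    }

    out <- list(
      genotypes = genotype_matrix(g, map),
      truth = structure(list(
        causal_interval = civ,
        causal_variant_position = config$causal_position,
        carrier_status = status,
        cases = cases,
        disease_founder = disease_founder,
        true_sigma_a2 = config$phenotype_sigma_a2,
        true_sigma_e2 = config$phenotype_sigma_e2,
        pedigree = ped2), class = "sim_truth"))
    if (keep_haplotypes) {
      rownames(H1) <- rownames(H2) <- ped2$animal_id
      out$haplotypes <- list(paternal = H1, maternal = H2, loci = loci,
                             causal_idx = causal_idx)
      out$geno_raw <- raw
    }
    out
  })
  res
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> causal %s:%s in %s; %d cases (%d phenocopies); %d AA / %d AG animals\n",
              x$causal_interval$chrom,
              format(x$causal_variant_position, scientific = FALSE),
              format(x$causal_interval),
              nrow(x$cases), sum(x$cases$phenocopy),
              sum(x$carrier_status == "AA"), sum(x$carrier_status == "AG")))
  invisible(x)
}
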