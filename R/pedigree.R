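#' Validate a pedigree table
#'
#' A pedigree is a `data.frame` with columns `animal_id`, `sire_id`,
#' `dam_id`, `sex` (`"M"`/`"F"` or NA) and `birth_cohort` (integer
#' generation index). Unknown parents are `NA` (read/written as `"0"` on
#' disk) and are treated as unrelated, non-inbred founders. Validation
#' checks id uniqueness, sex-of-parent consistency and acyclicity (every
#' animal must be orderable after both of its parents).
#'
#' @param ped pedigree `data.frame`.
#' @return the pedigree, invisibly, with parents coerced to character.
#' @export
validate_pedigree <- function(ped) {
  need <- c("animal_id", "sire_id", "dam_id")
  if (!all(need %in% names(ped))) {
    stop("pedigree must have columns animal_id, sire_id, dam_id", call. = FALSE)
  }
  ped$animal_id <- as.character(ped$animal_id)
  ped$sire_id <- as.character(ped$sire_id)
  ped$dam_id <- as.character(ped$dam_id)
  ped$sire_id[ped$sire_id %in% c("0", "")] <- NA_character_
  ped$dam_id[ped$dam_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$animal_id)) {
    stop("duplicate animal_id in pedigree", call. = FALSE)
  }
  if (any(ped$animal_id == ped$sire_id, na.rm = TRUE) ||
      any(ped$animal_id == ped$dam_id, na.rm = TRUE)) {
    stop("structural error: an animal is listed as its own parent", call. = FALSE)
  }
  if ("sex" %in% names(ped)) {
    sex <- setNames(as.character(ped$sex), ped$animal_id)
    sires <- unique(stats::na.omit(ped$sire_id))
    dams <- unique(stats::na.omit(ped$dam_id))
    bad_sire <- sires[!is.na(sex[sires]) & sex[sires] == "F"]
    bad_dam <- dams[!is.na(sex[dams]) & sex[dams] == "M"]
    if (length(bad_sire) || length(bad_dam)) {
      stop(sprintf("structural error: parent sex inconsistent for %s",
                   paste(c(bad_sire, bad_dam), collapse = ", ")), call. = FALSE)
    }
  }
  pedigree_order(ped) # errors on cycles
  invisible(ped)
}

#' Topological order of a pedigree (parents before offspring)
#'
#' Kahn's algorithm over the parent-offspring DAG; a cycle (an animal that is
#' its own ancestor) raises an error naming a cycle member.
#'
#' @param ped pedigree `data.frame`.
#' @return integer vector of row indices in a valid processing order.
#' @export
pedigree_order <- function(ped) {
  id <- as.character(ped$animal_id)
  idx <- setNames(seq_along(id), id)
  sire <- idx[as.character(ped$sire_id)]
  dam <- idx[as.character(ped$dam_id)]
  n <- length(id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    member <- id[setdiff(seq_len(n), out)][1L]
    stop(sprintf("structural error: pedigree contains a cycle involving '%s'",
                 member), call. = FALSE)
  }
  out
}

#' Expected founder genetic contributions
#'
#' The expected fraction of each animal's genome contributed by each founder,
#' by the standard recursion `c_f(i) = (c_f(sire) + c_f(dam)) / 2` with
#' unknown parents contributing a fresh (anonymous) founder genome.
#'
#' @param ped pedigree `data.frame`.
#' @return matrix animals x founders of expected contributions.
#' @export
founder_contributions <- function(ped) {
  ped <- validate_pedigree(ped)
  ord <- pedigree_order(ped)
  id <- ped$animal_id
  idx <- setNames(seq_along(id), id)
  founders <- id[is.na(ped$sire_id) & is.na(ped$dam_id)]
  C <- matrix(0, nrow = length(id), ncol = length(founders),
              dimnames = list(id, founders))
  for (i in ord) {
    if (is.na(ped$sire_id[i]) && is.na(ped$dam_id[i])) {
      C[i, id[i]] <- 1
    } else {
      s <- idx[ped$sire_id[i]]
      d <- idx[ped$dam_id[i]]
      cs <- if (!is.na(s)) C[s, ] else 0 # unknown parent: anonymous founder
      cd <- if (!is.na(d)) C[d, ] else 0
      C[i, ] <- (cs + cd) / 2
    }
  }
  C
}

#' Simulate a linebred multi-generation pedigree
#'
#' Founders form generation 0 (half male, half female); the first male
#' founder is the designated predominant ancestor. He sires a configured
#' share of generation-1 offspring (derived from the target carrier
#' frequency: with allele frequency q solving `2q(1-q) = target`, his
#' expected genomic contribution must be `2q`, i.e. a generation-1 siring
#' share of `4q`, capped at 0.9). Later generations mate uniformly within
#' the previous generation, which keeps expected founder contributions
#' constant. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return pedigree `data.frame` (`animal_id`, `sire_id`, `dam_id`, `sex`,
#'   `birth_cohort`) with attribute `predominant_founder`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- config$n_founders
  founders <- data.frame(
    animal_id = sprintf("F%03d", seq_len(nf)),
    sire_id = NA_character_, dam_id = NA_character_,
    sex = rep(c("M", "F"), length.out = nf),
    birth_cohort = 0L, stringsAsFactors = FALSE)
  pred <- founders$animal_id[founders$sex == "M"][1L]

  q <- (1 - sqrt(1 - 2 * config$target_carrier_frequency)) / 2
  share <- min(0.9, 4 * q)

  ped <- founders
  with_seed(config$seed, {
    if (config$n_generations >= 1L && config$n_offspring_per_gen >= 1L &&
        config$n_generations >= 2L) {
      for (g in seq_len(config$n_generations - 1L)) {
        prev <- ped[ped$birth_cohort == g - 1L, ]
        males <- prev$animal_id[prev$sex == "M"]
        females <- prev$animal_id[prev$sex == "F"]
        if (!length(males) || !length(females)) break
        n <- config$n_offspring_per_gen
        sire <- sample(males, n, replace = TRUE)
        if (g == 1L) {
          take <- runif(n) < share
          sire[take] <- pred
        }
        dam <- sample(females, n, replace = TRUE)
        kids <- data.frame(
          animal_id = sprintf("G%d_%04d", g, seq_len(n)),
          sire_id = sire, dam_id = dam,
          sex = sample(c("M", "F"), n, replace = TRUE),
          birth_cohort = g, stringsAsFactors = FALSE)
        ped <- rbind(ped, kids)
      }
    }
  })
  attr(ped, "predominant_founder") <- pred
  validate_pedigree(ped)
  ped
}
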