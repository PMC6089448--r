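#' Runs-of-homozygosity detection parameters
#'
#' Thresholds for [detect_roh()]. Defaults are tuned to 50K-array density:
#' a segment must span at least `min_markers` markers and `min_length_bp`
#' basepairs, and may absorb at most `max_het_calls` heterozygous and
#' `max_missing_calls` missing calls (genotyping-error tolerance).
#'
#' @param min_markers minimum markers per segment.
#' @param min_length_bp minimum genomic span (bp).
#' @param max_het_calls maximum heterozygous calls tolerated inside a segment.
#' @param max_missing_calls maximum missing calls tolerated inside a segment.
#' @param min_case_fraction minimum fraction of cases that must share an
#'   interval in [map_shared_interval()] (phenocopy tolerance).
#' @param require_shared_allele require all supporting cases to be homozygous
#'   for the same allele at informative markers.
#' @param max_discord_markers,max_discord_fraction consensus-haplotype
#'   tolerance in [map_shared_interval()]: a supporting case may contradict
#'   the consensus homozygous haplotype (mismatching homozygous calls plus
#'   heterozygous calls) at up to `max(max_discord_markers,
#'   ceiling(max_discord_fraction * informative markers))` positions before
#'   being declared discordant at that locus. Kept much tighter than the
#'   detection tolerances: segment detection must absorb error-induced
#'   breaks in megabase-scale runs, whereas haplotype identity is the
#'   discriminating signal and erodes quickly if relaxed.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_markers = 15L, min_length_bp = 5e5,
                       max_het_calls = 3L, max_missing_calls = 10L,
                       min_case_fraction = 0.85, require_shared_allele = TRUE,
                       max_discord_markers = 1L, max_discord_fraction = 0.10) {
  assert_count(min_markers, "min_markers", min = 1L)
  assert_count(max_het_calls, "max_het_calls")
  assert_count(max_missing_calls, "max_missing_calls")
  assert_count(max_discord_markers, "max_discord_markers")
  assert_prob(max_discord_fraction, "max_discord_fraction")
  assert_prob(min_case_fraction, "min_case_fraction")
  structure(list(min_markers = as.integer(min_markers),
                 min_length_bp = min_length_bp,
                 max_het_calls = as.integer(max_het_calls),
                 max_missing_calls = as.integer(max_missing_calls),
                 min_case_fraction = min_case_fraction,
                 require_shared_allele = isTRUE(require_shared_allele),
                 max_discord_markers = as.integer(max_discord_markers),
                 max_discord_fraction = max_discord_fraction),
            class = "roh_params")
}

# Maximal qualifying runs on one chromosome for one sample.
# A qualifying window: <= max_het hets, <= max_miss missing, homozygous
# non-missing endpoints. Two-pointer scan: for each right end j (homozygous),
# L(j) = smallest feasible start; trimmed to the first homozygous marker.
# Maximal windows are those not contained in a later (wider) one.
roh_runs_chrom <- function(codes, pos, params) {
  n <- length(codes)
  het <- !is.na(codes) & codes == 1L
  mis <- is.na(codes)
  hom <- !het & !mis
  if (!any(hom)) return(NULL)
  cum_het <- cumsum(het)
  cum_mis <- cumsum(mis)
  L <- 1L
  cand_start <- integer(0); cand_end <- integer(0)
  hom_from <- integer(n) # first homozygous index >= i
  nxt <- NA_integer_
  for (i in n:1) {
    if (hom[i]) nxt <- i
    hom_from[i] <- if (is.na(nxt)) NA_integer_ else nxt
  }
  for (j in seq_len(n)) {
    if (!hom[j]) next
    # advance L until window [L, j] feasible
    while (TRUE) {
      nh <- cum_het[j] - if (L > 1L) cum_het[L - 1L] else 0L
      nm <- cum_mis[j] - if (L > 1L) cum_mis[L - 1L] else 0L
      if (nh <= params$max_het_calls && nm <= params$max_missing_calls) break
      L <- L + 1L
    }
    s <- hom_from[L]
    if (is.na(s) || s > j) next
    k <- length(cand_start)
    if (k > 0L && cand_start[k] == s) {
      cand_end[k] <- j # same start, wider window supersedes
    } else {
      cand_start <- c(cand_start, s); cand_end <- c(cand_end, j)
    }
  }
  keep <- rep(TRUE, length(cand_start))
  # drop windows contained in a later one (starts are non-decreasing)
  if (length(cand_start) > 1L) {
    for (k in seq_len(length(cand_start) - 1L)) {
      if (cand_end[k] <= cand_end[k + 1L] && cand_start[k] >= cand_start[k + 1L]) {
        keep[k] <- FALSE
      }
    }
  }
  cand_start <- cand_start[keep]; cand_end <- cand_end[keep]
  ok <- (cand_end - cand_start + 1L) >= params$min_markers &
    (pos[cand_end] - pos[cand_start]) >= params$min_length_bp
  if (!any(ok)) return(NULL)
  data.frame(start_idx = cand_start[ok], end_idx = cand_end[ok])
}

#' Detect runs of homozygosity for one sample
#'
#' Maximal marker runs in which heterozygous and missing calls stay within
#' the configured tolerances, trimmed to homozygous endpoints and reported
#' with genomic bounds at the first and last marker of the run.
#'
#' @param genotypes a [genotype_matrix()].
#' @param sample sample id.
#' @param params a [roh_params()].
#' @return `data.frame` with one row per segment: `sample`, `chrom`,
#'   `start_bp`, `end_bp`, `start_idx`, `end_idx` (column indices into the
#'   map), `n_markers`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(genotypes, sample, params = roh_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(params, "roh_params"))
  if (!sample %in% rownames(genotypes$geno)) {
    stop(sprintf("lookup error: unknown sample '%s'", sample), call. = FALSE)
  }
  map <- genotypes$map
  codes <- genotypes$geno[sample, ]
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    runs <- roh_runs_chrom(codes[sel], map$pos_bp[sel], params)
    if (is.null(runs)) next
    gi <- sel[runs$start_idx]; gj <- sel[runs$end_idx]
    seg <- data.frame(
      sample = sample, chrom = ch,
      start_bp = map$pos_bp[gi], end_bp = map$pos_bp[gj],
      start_idx = gi, end_idx = gj,
      n_markers = gj - gi + 1L,
      stringsAsFactors = FALSE)
    seg$n_het <- vapply(seq_len(nrow(seg)), function(r) {
      sum(codes[gi[r]:gj[r]] == 1L, na.rm = TRUE)
    }, integer(1))
    seg$n_missing <- vapply(seq_len(nrow(seg)), function(r) {
      sum(is.na(codes[gi[r]:gj[r]]))
    }, integer(1))
    out[[ch]] <- seg
  }
  if (!length(out)) {
    return(data.frame(sample = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      start_idx = integer(), end_idx = integer(),
                      n_markers = integer(), n_het = integer(),
                      n_missing = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map the shared autozygosity interval across cases
#'
#' Detects ROH per case, then treats every marker covered by segments from
#' at least `min_case_fraction` of cases as a candidate anchor. At each
#' anchor, supporting cases are those whose segment covers it and the shared
#' interval is the intersection of their segments. With
#' `require_shared_allele`, haplotype analysis refines the support: cases
#' contradicting the per-marker consensus homozygous allele beyond the
#' discordance tolerance (a different autozygous haplotype, or heterozygous
#' stretches inside the interval) are moved to the discordant set and the
#' intersection is recomputed; candidates whose support falls below the case
#' fraction, or whose span falls below `min_length_bp`, are rejected.
#' Identical candidates from neighbouring anchors are merged; the survivors
#' are ranked by supporting-case count, then marker count, then length.
#'
#' @param genotypes a [genotype_matrix()].
#' @param case_ids ids of affected animals (>= 2).
#' @param params a [roh_params()].
#' @return list with `intervals` (ranked `data.frame`: `chrom`, `start_bp`,
#'   `end_bp`, `n_support`, `n_markers`, `length_bp`, `shared_allele_consistent`,
#'   `supporting` and `discordant` as comma-joined id strings) and
#'   `diagnostics`. An empty `intervals` table (with `diagnostics` explaining
#'   why) is returned when nothing qualifies - not an exception.
#' @export
map_shared_interval <- function(genotypes, case_ids, params = roh_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(case_ids) < 2L) stop("need at least two cases", call. = FALSE)
  missing_ids <- setdiff(case_ids, rownames(genotypes$geno))
  if (length(missing_ids)) {
    stop(sprintf("lookup error: unknown case sample(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  map <- genotypes$map
  segs <- do.call(rbind, lapply(case_ids, detect_roh,
                                genotypes = genotypes, params = params))
  need <- ceiling(params$min_case_fraction * length(case_ids))
  empty <- data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
                      n_support = integer(), n_markers = integer(),
                      length_bp = numeric(), shared_allele_consistent = logical(),
                      supporting = character(), discordant = character())
  if (is.null(segs) || nrow(segs) == 0L) {
    return(list(intervals = empty,
                diagnostics = "no ROH segment detected in any case"))
  }
  results <- list()
  seen <- character(0)
  for (ch in unique(segs$chrom)) {
    sel <- which(map$chrom == ch)
    cover <- matrix(FALSE, length(case_ids), length(sel),
                    dimnames = list(case_ids, NULL))
    schrom <- segs[segs$chrom == ch, ]
    off <- sel[1L] - 1L
    for (r in seq_len(nrow(schrom))) {
      span <- (schrom$start_idx[r]:schrom$end_idx[r]) - off
      cover[schrom$sample[r], span] <- TRUE
    }
    cov <- colSums(cover)
    anchors <- which(cov >= need)
    if (!length(anchors)) next
    # every qualifying marker anchors a candidate: the cases covering it and
    # the intersection of their segments; identical intervals are merged, so
    # each distinct support configuration yields one candidate
    for (a in anchors) {
      support <- case_ids[cover[, a]]
      intersect_support <- function(support) {
        lo <- 1L; hi <- length(sel)
        for (cs in support) {
          seg <- schrom[schrom$sample == cs, ]
          seg <- seg[(seg$start_idx - off) <= a & (seg$end_idx - off) >= a, ][1L, ]
          lo <- max(lo, seg$start_idx - off)
          hi <- min(hi, seg$end_idx - off)
        }
        c(lo, hi)
      }
      rng <- intersect_support(support)
      int_lo <- rng[1]; int_hi <- rng[2]
      consistent <- TRUE
      if (params$require_shared_allele && int_lo <= int_hi) {
        # haplotype analysis: supporting cases must be homozygous for a
        # shared consensus haplotype across the interval. Cases conflicting
        # with the per-marker majority allele at more markers than the
        # genotyping-error allowance are discordant at this anchor (their
        # autozygous haplotype is a different one); the intersection is
        # recomputed over the consistent cases.
        for (pass in 1:2) {
          sub <- genotypes$geno[support, sel[int_lo:int_hi], drop = FALSE]
          hom0 <- colSums(sub == 0L, na.rm = TRUE)
          hom2 <- colSums(sub == 2L, na.rm = TRUE)
          consensus <- ifelse(hom0 > hom2, 0L, ifelse(hom2 > hom0, 2L, NA_integer_))
          cons_mat <- matrix(consensus, nrow(sub), ncol(sub), byrow = TRUE)
          informative <- !is.na(sub) & sub != 1L & !is.na(cons_mat)
          mismatch <- informative & sub != cons_mat
          # heterozygous calls inside the interval argue directly against
          # autozygosity there and count as discordance alongside
          # consensus mismatches
          n_conf <- rowSums(mismatch) + rowSums(!is.na(sub) & sub == 1L)
          # tolerance scales with the informative-marker count: a case whose
          # own autozygous tract extends past the shared haplotype mismatches
          # at a few edge markers, whereas a different haplotype mismatches
          # at about half of them
          tol <- pmax(params$max_discord_markers,
                      ceiling(params$max_discord_fraction * rowSums(informative)))
          ok_cases <- n_conf <= tol
          if (all(ok_cases)) break
          support <- support[ok_cases]
          if (length(support) < need) { consistent <- FALSE; break }
          rng <- intersect_support(support)
          int_lo <- rng[1]; int_hi <- rng[2]
          if (int_lo > int_hi) { consistent <- FALSE; break }
        }
        if (consistent) {
          # residual two-sided conflicts (should be rare): trim to the
          # maximal conflict-free run containing the anchor
          sub <- genotypes$geno[support, sel[int_lo:int_hi], drop = FALSE]
          hom0 <- colSums(sub == 0L, na.rm = TRUE)
          hom2 <- colSums(sub == 2L, na.rm = TRUE)
          conflict <- hom0 > 0L & hom2 > 0L
          if (any(conflict)) {
            rel <- a - int_lo + 1L
            if (conflict[rel]) { consistent <- FALSE } else {
              lft <- rel
              while (lft > 1L && !conflict[lft - 1L]) lft <- lft - 1L
              rgt <- rel
              while (rgt < length(conflict) && !conflict[rgt + 1L]) rgt <- rgt + 1L
              int_hi <- int_lo + rgt - 1L
              int_lo <- int_lo + lft - 1L
            }
          }
        }
      }
      if (!consistent || int_lo > int_hi || length(support) < need) next
      # a credible shared interval must satisfy the same genomic-span
      # threshold as the per-sample segments; marker-thin chance overlaps
      # (e.g. one phenocopy haplotype coinciding over a few markers) fail it
      if (map$pos_bp[sel[int_hi]] - map$pos_bp[sel[int_lo]] < params$min_length_bp) next
      key <- sprintf("%s:%d-%d:%s", ch, int_lo, int_hi,
                     paste(sort(support), collapse = "|"))
      if (key %in% seen) next
      seen <- c(seen, key)
      gi <- sel[int_lo]; gj <- sel[int_hi]
      results[[length(results) + 1L]] <- data.frame(
        chrom = ch, start_bp = map$pos_bp[gi], end_bp = map$pos_bp[gj],
        n_support = length(support), n_markers = gj - gi + 1L,
        length_bp = map$pos_bp[gj] - map$pos_bp[gi],
        shared_allele_consistent = consistent,
        supporting = paste(support, collapse = ","),
        discordant = paste(setdiff(case_ids, support), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(results)) {
    return(list(intervals = empty,
                diagnostics = sprintf(
                  "no interval shared by >= %d of %d cases under the criteria",
                  need, length(case_ids))))
  }
  tab <- do.call(rbind, results)
  tab <- tab[order(-tab$n_support, -tab$n_markers, -tab$length_bp), ]
  rownames(tab) <- NULL
  list(intervals = tab,
       diagnostics = sprintf("%d candidate interval(s); support threshold %d/%d cases",
                             nrow(tab), need, length(case_ids)))
}
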