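#' Case/control variant filtering cascade
#'
#' Applies, in order, the five-step prioritization used for a recessive
#' candidate from a small sequencing design:
#'
#' 1. restrict to the mapped autozygosity interval;
#' 2. genotype segregation: homozygous alternate in ALL cases AND not
#'    homozygous alternate in controls (all controls by default; a missing
#'    call in a case fails the criterion - conservative);
#' 3. drop variants present in the catalogue of known polymorphisms;
#' 4. drop variants present on the SNP array in other breeds;
#' 5. keep protein-altering consequences (`missense`, `stop_gain`,
#'    `stop_loss`, `start_loss`, `frameshift`); synonymous and non-coding
#'    classes are dropped. Optionally, a synonymous variant in a donor
#'    splice region whose PWM score drop exceeds a threshold is retained
#'    (`keep_splice_synonymous`), since an exon-terminal substitution can
#'    damage splicing without changing the protein.
#'
#' Consequences are taken from a `consequence` column when present,
#' otherwise computed with [annotate_consequence()] against the supplied
#' transcripts and genome.
#'
#' @param variants variant `data.frame` (see [simulate_variant_table()] or
#'   [read_vcf()]): `chrom`, `pos`, `ref`, `alt`, per-sample genotype
#'   columns with values `hom_ref/het/hom_alt/missing`, logical
#'   `known_in_catalogue`, `on_array_other_breeds`.
#' @param case_ids,control_ids genotype column names for cases/controls.
#' @param interval a [genomic_interval()].
#' @param transcripts list of [transcript_model()] (used when no
#'   `consequence` column is present).
#' @param genome genome list for annotation (with `transcripts`).
#' @param control_mode `"all"` (default: every control must lack hom-alt) or
#'   `"any"` (at least one control lacks it).
#' @param keep_splice_synonymous retain synonymous donor splice-region
#'   variants with PWM delta at or below `-splice_delta_threshold`.
#' @param splice_delta_threshold bits of donor-score drop required (default 1).
#' @param pwm a [splice_pwm()] for the synonymous-splice rescue.
#' @return list with `survivors` (filtered `data.frame`), `report`
#'   (`data.frame`: `step`, `n_in`, `n_out`) and `failed_step` (named by
#'   `variant_id` where available: the first failing step of each dropped
#'   variant).
#' @export
apply_filter_cascade <- function(variants, case_ids, control_ids, interval,
                                 transcripts = NULL, genome = NULL,
                                 control_mode = c("all", "any"),
                                 keep_splice_synonymous = FALSE,
                                 splice_delta_threshold = 1,
                                 pwm = default_donor_pwm()) {
  control_mode <- match.arg(control_mode)
  if (length(case_ids) < 1L) stop("configuration error: empty case list", call. = FALSE)
  if (length(control_ids) < 1L) stop("configuration error: empty control list",
                                     call. = FALSE)
  stopifnot(inherits(interval, "genomic_interval"))
  v <- variants
  if (nrow(v) > 0 && is.unsorted(order(v$chrom, v$pos))) {
    # defensive; ordering does not change set semantics
    v <- v[order(v$chrom, v$pos), ]
  }
  ids <- if ("variant_id" %in% names(v)) v$variant_id else
    sprintf("%s_%s_%s_%s", v$chrom, v$pos, v$ref, v$alt)
  failed <- setNames(rep(NA_character_, nrow(v)), ids)

  steps <- c("in_interval", "segregation", "not_in_catalogue",
             "not_on_array", "protein_altering")
  report <- data.frame(step = steps, n_in = NA_integer_, n_out = NA_integer_)
  keep <- rep(TRUE, nrow(v))

  mark <- function(keep, pass, step) {
    drop_now <- keep & !pass
    failed[ids[drop_now]] <<- step
    keep & pass
  }

  # 1: interval restriction
  report$n_in[1] <- nrow(v)
  pass <- in_interval(v$chrom, v$pos, interval)
  keep <- mark(keep, pass, "in_interval")
  report$n_out[1] <- sum(keep)

  # 2: segregation
  report$n_in[2] <- sum(keep)
  case_ok <- Reduce(`&`, lapply(case_ids, function(cid) {
    g <- v[[cid]]
    !is.na(g) & g == "hom_alt" # missing fails
  }), rep(TRUE, nrow(v)))
  ctrl_not_homalt <- lapply(control_ids, function(cid) {
    g <- v[[cid]]
    is.na(g) | g != "hom_alt" # "absent or heterozygous": missing passes
  })
  ctrl_ok <- if (control_mode == "all") Reduce(`&`, ctrl_not_homalt) else
    Reduce(`|`, ctrl_not_homalt)
  keep <- mark(keep, case_ok & ctrl_ok, "segregation")
  report$n_out[2] <- sum(keep)

  # 3: known catalogue
  report$n_in[3] <- sum(keep)
  keep <- mark(keep, !isTRUE_vec(v$known_in_catalogue, nrow(v)), "not_in_catalogue")
  report$n_out[3] <- sum(keep)

  # 4: array content of other breeds
  report$n_in[4] <- sum(keep)
  keep <- mark(keep, !isTRUE_vec(v$on_array_other_breeds, nrow(v)), "not_on_array")
  report$n_out[4] <- sum(keep)

  # 5: protein-altering consequence
  report$n_in[5] <- sum(keep)
  protein_altering <- c("missense", "stop_gain", "stop_loss", "start_loss",
                        "frameshift")
  cons <- vector("list", nrow(v))
  if ("consequence" %in% names(v)) {
    cons <- strsplit(as.character(v$consequence), "[,+&]")
  } else {
    if (is.null(transcripts) || is.null(genome)) {
      stop("need a consequence column, or transcripts + genome to annotate",
           call. = FALSE)
    }
    for (i in which(keep)) {
      calls <- lapply(transcripts, function(tm) {
        annotate_consequence(v[i, ], tm, genome)$class
      })
      cons[[i]] <- unique(unlist(calls))
    }
  }
  pass5 <- vapply(seq_len(nrow(v)), function(i) {
    cl <- cons[[i]]
    if (is.null(cl) || !length(cl)) return(FALSE)
    if (any(cl %in% protein_altering)) return(TRUE)
    if (keep_splice_synonymous && "synonymous" %in% cl && "splice_region" %in% cl &&
        !is.null(v$donor_delta[i]) && !is.na(v$donor_delta[i]) &&
        v$donor_delta[i] <= -splice_delta_threshold) return(TRUE)
    FALSE
  }, logical(1))
  keep <- mark(keep, pass5, "protein_altering")
  report$n_out[5] <- sum(keep)

  list(survivors = v[keep, , drop = FALSE], report = report,
       failed_step = failed[!is.na(failed)])
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else !is.na(x) & as.logical(x)
}
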