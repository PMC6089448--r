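#' Simulate a sequencing variant table around the causal interval
#'
#' Emulates the variant calls of a small sequencing design (two affected,
#' one unaffected animal): one planted causal variant (homozygous alternate
#' in both affected animals, not in the control, absent from the catalogue
#' and the array, protein-altering) plus background variants each engineered
#' to pass every cascade criterion before its designated one and fail
#' exactly there. Category counts are recorded so the filter cascade can be
#' checked against truth by construction. Default counts reproduce the shape
#' of the published cascade (1503 in-interval variants thinning to a single
#' non-synonymous survivor).
#'
#' @param truth a `sim_truth` from [gene_drop()] (used for the causal
#'   interval and position), or NULL to use `config` directly.
#' @param config a [sim_config()].
#' @param n_cases,n_controls sequenced animals (the study design is 2 + 1).
#' @param seed overrides `config$seed` when not NULL.
#' @return list with `variants` (a `data.frame`: `chrom`, `pos`, `ref`,
#'   `alt`, one genotype column per sequenced animal with values in
#'   `{hom_ref, het, hom_alt, missing}`, `known_in_catalogue`,
#'   `on_array_other_breeds`, `consequence`, `category`) and
#'   `category_counts` (named integer vector, the bookkeeping truth).
#' @export
simulate_variant_table <- function(truth = NULL, config = sim_config(),
                                   n_cases = 2L, n_controls = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cases < 1L) stop("input error: need at least one affected sequenced animal",
                         call. = FALSE)
  if (n_controls < 1L) stop("input error: need at least one control animal",
                            call. = FALSE)
  civ <- if (!is.null(truth)) truth$causal_interval else config$causal_interval
  cpos <- if (!is.null(truth)) truth$causal_variant_position else config$causal_position
  case_ids <- sprintf("CASE_SEQ%d", seq_len(n_cases))
  control_ids <- sprintf("CTRL_SEQ%d", seq_len(n_controls))

  counts <- c(outside_interval = config$n_background_outside,
              fails_genotype = config$n_background_genotype,
              known_in_catalogue = config$n_background_known,
              on_array = config$n_background_array,
              not_protein_altering = config$n_background_nonprotein,
              causal = 1L)

  bases <- c("A", "C", "G", "T")
  protein_altering <- c("missense", "stop_gain", "frameshift")
  neutral_cons <- c("synonymous", "intronic")

  with_seed(seed %||% (config$seed + 3L), {
    # draw all positions up front, without replacement, so no two variants
    # collide and the conservation invariant (emitted = causal + sum of
    # background counts) holds exactly
    n_inside <- sum(counts[c("fails_genotype", "known_in_catalogue", "on_array",
                             "not_protein_altering")])
    pos_inside <- sample(setdiff(seq(civ$start, civ$end), cpos), n_inside)
    pos_outside <- sample(c(seq(max(1, civ$start - 2e6), civ$start - 1),
                            seq(civ$end + 1, civ$end + 2e6)),
                          counts[["outside_interval"]])
    inside_used <- 0L
    mk <- function(n, category) {
      if (n == 0L) return(NULL)
      if (category == "outside_interval") {
        pos <- pos_outside
      } else {
        pos <- pos_inside[inside_used + seq_len(n)]
        inside_used <<- inside_used + n
      }
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      df <- data.frame(chrom = civ$chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
      # genotype layout: pass the case/control criterion unless this is the
      # category engineered to fail it
      for (cid in case_ids) df[[cid]] <- "hom_alt"
      for (cid in control_ids) df[[cid]] <- sample(c("hom_ref", "het"), n, replace = TRUE)
      if (category == "fails_genotype") {
        fail_mode <- sample(3L, n, replace = TRUE)
        df[[case_ids[1L]]][fail_mode == 1L] <- "het"
        df[[case_ids[length(case_ids)]]][fail_mode == 2L] <- "hom_ref"
        for (cid in control_ids) df[[cid]][fail_mode == 3L] <- "hom_alt"
      }
      df$known_in_catalogue <- category == "known_in_catalogue"
      df$on_array_other_breeds <- category == "on_array"
      df$consequence <- if (category == "not_protein_altering") {
        sample(neutral_cons, n, replace = TRUE)
      } else {
        # non-causal categories get a mix of classes; they fail earlier steps
        sample(c(protein_altering, neutral_cons), n, replace = TRUE)
      }
      df$category <- category
      df
    }
    parts <- lapply(names(counts)[names(counts) != "causal"],
                    function(ct) mk(counts[[ct]], ct))
    causal <- data.frame(chrom = civ$chrom, pos = cpos, ref = "C", alt = "T",
                         stringsAsFactors = FALSE)
    for (cid in case_ids) causal[[cid]] <- "hom_alt"
    for (cid in control_ids) causal[[cid]] <- "het"
    causal$known_in_catalogue <- FALSE
    causal$on_array_other_breeds <- FALSE
    causal$consequence <- "missense"
    causal$category <- "causal"
    variants <- do.call(rbind, c(parts, list(causal)))
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL
    variants$variant_id <- sprintf("%s_%d_%s_%s", variants$chrom, variants$pos,
                                   variants$ref, variants$alt)
    list(variants = variants,
         category_counts = vapply(split(variants$category, variants$category),
                                  length, integer(1)),
         case_ids = case_ids, control_ids = control_ids,
         causal_id = sprintf("%s_%d_C_T", civ$chrom, as.integer(cpos)))
  })
}
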