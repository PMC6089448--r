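#' Predict the coding/splice consequence of a variant on a transcript
#'
#' Locates the variant in the transcript model, translates affected codons
#' with the standard genetic code (reverse-strand transcripts are handled by
#' complementing alleles and reversing exon order before codon lookup), and
#' flags splice-region proximity: by default the donor-side window covers
#' the last `splice_exonic` bases of each non-terminal exon and the first
#' `splice_intronic` bases of the following intron; an acceptor-side window
#' can be enabled.
#'
#' Classes are multi-label: a substitution at an exon-terminal codon base
#' can be simultaneously `missense` and `splice_region`, which is exactly
#' the configuration of interest for an exon-skipping candidate.
#'
#' @param variant list or one-row `data.frame` with `chrom`, `pos`, `ref`,
#'   `alt` (genomic forward-strand alleles, VCF convention).
#' @param transcript a [transcript_model()].
#' @param genome named list of chromosome sequences (strings or
#'   `genome_slice()` objects) covering the transcript span.
#' @param splice_exonic,splice_intronic donor-window widths (bases).
#' @param acceptor_window also flag acceptor-side proximity (last
#'   `splice_intronic` intronic / first `splice_exonic` exonic bases).
#' @return list of class `consequence_call`: `class` (character vector),
#'   `protein_change` (HGVS-like, NA for non-CDS), `exon_index`
#'   (transcription order, NA if intronic/intergenic),
#'   `distance_to_exon_boundary`, `codon_index`, `ref_codon`, `alt_codon`.
#' @export
annotate_consequence <- function(variant, transcript, genome,
                                 splice_exonic = 3L, splice_intronic = 6L,
                                 acceptor_window = FALSE) {
  tm <- transcript
  v <- as.list(variant)
  v$pos <- as.numeric(v$pos)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (!identical(as.character(v$chrom), tm$chrom) ||
      v$pos < min(tm$exons$start) || v$pos > max(tm$exons$end)) {
    return(structure(list(class = "intergenic", protein_change = NA_character_,
                          exon_index = NA_integer_,
                          distance_to_exon_boundary = NA_integer_,
                          codon_index = NA_integer_, ref_codon = NA_character_,
                          alt_codon = NA_character_), class = "consequence_call"))
  }

  ne <- nrow(tm$exons)
  # exon index in transcription order
  exon_genomic <- which(v$pos >= tm$exons$start & v$pos <= tm$exons$end)
  tx_index <- function(gi) if (tm$strand == "+") gi else ne - gi + 1L

  # donor-side splice window membership and signed distance to the boundary
  splice <- FALSE
  dist_boundary <- NA_integer_
  for (gi in seq_len(ne)) {
    if (tm$strand == "+") {
      donor_edge <- tm$exons$end[gi]
      is_last <- gi == ne
      if (!is_last) {
        if (v$pos >= donor_edge - splice_exonic + 1 && v$pos <= donor_edge) {
          splice <- TRUE; dist_boundary <- as.integer(donor_edge - v$pos)
        } else if (v$pos > donor_edge && v$pos <= donor_edge + splice_intronic) {
          splice <- TRUE; dist_boundary <- as.integer(v$pos - donor_edge)
        }
      }
      if (acceptor_window && gi > 1L) {
        acc_edge <- tm$exons$start[gi]
        if (v$pos >= acc_edge && v$pos <= acc_edge + splice_exonic - 1) {
          splice <- TRUE; dist_boundary <- as.integer(v$pos - acc_edge)
        } else if (v$pos < acc_edge && v$pos >= acc_edge - splice_intronic) {
          splice <- TRUE; dist_boundary <- as.integer(acc_edge - v$pos)
        }
      }
    } else {
      donor_edge <- tm$exons$start[gi] # 3' end of exon in transcript sense
      is_last <- tx_index(gi) == ne
      if (!is_last) {
        if (v$pos <= donor_edge + splice_exonic - 1 && v$pos >= donor_edge) {
          splice <- TRUE; dist_boundary <- as.integer(v$pos - donor_edge)
        } else if (v$pos < donor_edge && v$pos >= donor_edge - splice_intronic) {
          splice <- TRUE; dist_boundary <- as.integer(donor_edge - v$pos)
        }
      }
      if (acceptor_window && tx_index(gi) > 1L) {
        acc_edge <- tm$exons$end[gi]
        if (v$pos <= acc_edge && v$pos >= acc_edge - splice_exonic + 1) {
          splice <- TRUE; dist_boundary <- as.integer(acc_edge - v$pos)
        } else if (v$pos > acc_edge && v$pos <= acc_edge + splice_intronic) {
          splice <- TRUE; dist_boundary <- as.integer(v$pos - acc_edge)
        }
      }
    }
  }

  base_call <- function(cls, protein = NA_character_, codon_index = NA_integer_,
                        ref_codon = NA_character_, alt_codon = NA_character_) {
    if (splice) cls <- c(cls, "splice_region")
    structure(list(class = cls, protein_change = protein,
                   exon_index = if (length(exon_genomic)) tx_index(exon_genomic) else NA_integer_,
                   distance_to_exon_boundary = dist_boundary,
                   codon_index = codon_index, ref_codon = ref_codon,
                   alt_codon = alt_codon), class = "consequence_call")
  }

  if (!length(exon_genomic)) return(base_call("intronic"))

  cds_tx <- cds_positions_tx(tm)
  ci <- match(v$pos, cds_tx)
  if (is.na(ci)) return(base_call("intronic")) # exonic but non-coding

  # indels: frameshift vs in-frame by length difference
  if (nchar(v$ref) != nchar(v$alt)) {
    cls <- if ((nchar(v$ref) - nchar(v$alt)) %% 3L == 0L) "inframe_indel" else "frameshift"
    prot <- sprintf("p.%s%dfs", AA3[[translate_codon(
      paste(vapply(cds_tx[3L * ((ci - 1L) %/% 3L) + 1:3], fetch_tx_base,
                   character(1), tm = tm, genome = genome), collapse = ""))]],
      (ci - 1L) %/% 3L + 1L)
    return(base_call(cls, protein = if (cls == "frameshift") prot else NA_character_,
                     codon_index = (ci - 1L) %/% 3L + 1L))
  }

  codon_index <- (ci - 1L) %/% 3L + 1L
  within <- (ci - 1L) %% 3L + 1L
  codon_pos <- cds_tx[(codon_index - 1L) * 3L + 1:3]
  ref_codon <- paste(vapply(codon_pos, fetch_tx_base, character(1),
                            tm = tm, genome = genome), collapse = "")
  alt_base_tx <- if (tm$strand == "-") comp_base(v$alt) else v$alt
  ref_base_tx <- if (tm$strand == "-") comp_base(v$ref) else v$ref
  if (substr(ref_codon, within, within) != ref_base_tx) {
    stop(sprintf("reference mismatch at %s:%s (genome has '%s', variant ref '%s')",
                 v$chrom, format(v$pos, scientific = FALSE),
                 substr(ref_codon, within, within), ref_base_tx), call. = FALSE)
  }
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base_tx
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  cls <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else if (codon_index == 1L && aa_ref == "M") "start_loss"
    else "missense"
  prot <- if (aa_ref == aa_alt) {
    sprintf("p.%s%d=", AA3[[aa_ref]], codon_index)
  } else {
    sprintf("p.%s%d%s", AA3[[aa_ref]], codon_index, AA3[[aa_alt]])
  }
  base_call(cls, protein = prot, codon_index = codon_index,
            ref_codon = ref_codon, alt_codon = alt_codon)
}

# transcript-sense base at a genomic CDS position
fetch_tx_base <- function(pos, tm, genome) {
  b <- genome_fetch(genome, tm$chrom, pos, pos)
  if (tm$strand == "-") comp_base(b) else toupper(b)
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence_call> %s%s exon %s, codon %s %s>%s\n",
              paste(x$class, collapse = "+"),
              if (is.na(x$protein_change)) "" else paste0(" ", x$protein_change),
              x$exon_index, x$codon_index,
              x$ref_codon %||% "", x$alt_codon %||% ""),
      sep = "")
  invisible(x)
}
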