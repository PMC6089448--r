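#' Minimal transcript model
#'
#' A single-transcript gene model: ordered non-overlapping exons on one
#' chromosome, a CDS span inside the exon union, and a reading-frame offset.
#' Exons are stored in genomic order; for reverse-strand genes translation
#' runs from the highest-coordinate exon downwards on the complemented
#' sequence.
#'
#' @param gene_id gene label.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with 1-based inclusive `start`, `end` columns.
#' @param cds_start,cds_end genomic CDS bounds (1-based inclusive); defaults
#'   to the full exon span.
#' @param frame_offset bases to skip at the CDS 5' end before the first
#'   codon (usually 0).
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, chrom, strand, exons,
                             cds_start = min(exons$start),
                             cds_end = max(exons$end),
                             frame_offset = 0L) {
  stopifnot(strand %in% c("+", "-"), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end")]
  if (any(exons$end < exons$start)) stop("model error: exon end < start", call. = FALSE)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("model error: exons overlap", call. = FALSE)
  }
  if (cds_start < min(exons$start) || cds_end > max(exons$end) || cds_start > cds_end) {
    stop("model error: CDS outside exon span", call. = FALSE)
  }
  tm <- structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start, cds_end = cds_end,
                       frame_offset = as.integer(frame_offset)),
                  class = "transcript_model")
  n_cds <- length(cds_positions(tm)) - tm$frame_offset
  if (n_cds %% 3L != 0L) {
    stop("model error: CDS length not divisible by 3 after frame offset",
         call. = FALSE)
  }
  tm
}

# genomic positions of CDS bases, in genomic order
cds_positions <- function(tm) {
  pos <- unlist(lapply(seq_len(nrow(tm$exons)), function(i) {
    seq(tm$exons$start[i], tm$exons$end[i])
  }))
  pos[pos >= tm$cds_start & pos <= tm$cds_end]
}

# CDS positions in translation (transcript) order
cds_positions_tx <- function(tm) {
  pos <- cds_positions(tm)
  if (tm$strand == "-") pos <- rev(pos)
  if (tm$frame_offset > 0L) pos <- pos[-seq_len(tm$frame_offset)]
  pos
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s(%s) %d exon(s), CDS %s-%s\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              format(x$cds_start, scientific = FALSE),
              format(x$cds_end, scientific = FALSE)))
  invisible(x)
}

# --- genome representation helpers ---------------------------------------
# A genome is a named list, one element per chromosome: either a bare
# character string (coordinate 1 = first character) or list(seq=, start=)
# for a slice beginning at genomic coordinate `start`.

genome_slice <- function(seq, start = 1L) list(seq = seq, start = as.numeric(start))

genome_fetch <- function(genome, chrom, from, to) {
  g <- genome[[chrom]]
  if (is.null(g)) stop(sprintf("no sequence for chromosome '%s'", chrom), call. = FALSE)
  if (is.character(g)) g <- list(seq = g, start = 1)
  i <- from - g$start + 1
  j <- to - g$start + 1
  if (i < 1 || j > nchar(g$seq)) {
    stop(sprintf("genome sequence does not cover %s:%s-%s", chrom,
                 format(from, scientific = FALSE), format(to, scientific = FALSE)),
         call. = FALSE)
  }
  substr(g$seq, i, j)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

comp_base <- function(b) unname(COMPLEMENT[toupper(b)])

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "*")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}
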