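#' Build a toy spliced gene with a known CDS
#'
#' Constructs a genome slice, transcript model and coordinate maps for a
#' synthetic single-transcript gene: the supplied CDS (transcript sense) is
#' split into exons at the given transcript-coordinate boundaries, canonical
#' introns (`GT...AG`, donor `GTAAGT`) are inserted, and the whole locus is
#' laid onto the forward or reverse genomic strand. Used for annotator
#' validation and as the packaged stand-in (synthetic) for the real locus.
#'
#' @param cds coding sequence in transcript sense (length divisible by 3).
#' @param exon_ends transcript coordinates at which exons end (last must be
#'   `nchar(cds)`).
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome label.
#' @param intron_len intron length (>= 12; donor/acceptor motifs included).
#' @param g_start genomic coordinate of the locus slice start.
#' @param gene_id gene label.
#' @param seed seed for intron filler sequence.
#' @return list with `transcript` (a [transcript_model()]), `genome` (named
#'   list for [annotate_consequence()]), and `tx2gen(i)` mapping a CDS
#'   coordinate to its genomic position and forward-strand base.
#' @export
build_toy_gene <- function(cds, exon_ends, strand = "+", chrom = "chrT",
                           intron_len = 40L, g_start = 1001L,
                           gene_id = "TOY", seed = 42L) {
  cds <- toupper(cds)
  L <- nchar(cds)
  stopifnot(L %% 3L == 0L, exon_ends[length(exon_ends)] == L, intron_len >= 12L)
  n_ex <- length(exon_ends)
  ex_start_tx <- c(1L, utils::head(exon_ends, -1L) + 1L)
  introns <- with_seed(seed, {
    vapply(seq_len(max(n_ex - 1L, 0L)), function(i) {
      body <- paste(sample(c("A", "C", "G", "T"), intron_len - 12L, replace = TRUE),
                    collapse = "")
      paste0("GTAAGT", body, "TTTCAG")
    }, character(1))
  })
  pre <- ""
  tx2pre <- integer(L) # transcript (CDS) coord -> pre-mRNA coord
  off <- 0L
  for (i in seq_len(n_ex)) {
    idx <- ex_start_tx[i]:exon_ends[i]
    tx2pre[idx] <- idx + off
    pre <- paste0(pre, substr(cds, ex_start_tx[i], exon_ends[i]))
    if (i < n_ex) {
      pre <- paste0(pre, introns[i])
      off <- off + intron_len
    }
  }
  Lp <- nchar(pre)
  if (strand == "+") {
    gseq <- pre
    pre2gen <- function(t) g_start + t - 1
  } else {
    gseq <- revcomp(pre)
    pre2gen <- function(t) g_start + Lp - t
  }
  ex_g <- t(vapply(seq_len(n_ex), function(i) {
    a <- pre2gen(tx2pre[ex_start_tx[i]])
    b <- pre2gen(tx2pre[exon_ends[i]])
    c(min(a, b), max(a, b))
  }, numeric(2)))
  tm <- transcript_model(gene_id, chrom, strand,
                         data.frame(start = ex_g[, 1], end = ex_g[, 2]))
  genome <- setNames(list(genome_slice(gseq, g_start)), chrom)
  tx2gen <- function(i) {
    pos <- pre2gen(tx2pre[i])
    base_tx <- substr(cds, i, i)
    list(pos = pos,
         ref = if (strand == "-") comp_base(base_tx) else base_tx,
         base_tx = base_tx)
  }
  list(transcript = tm, genome = genome, tx2gen = tx2gen, cds = cds,
       strand = strand, chrom = chrom)
}

# deterministic non-stop codon filler
random_codons <- function(n, seed) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  with_seed(seed, paste(sample(codons, n, replace = TRUE), collapse = ""))
}

#' Packaged toy model of the bovine ataxia locus (synthetic)
#'
#' A synthetic reverse-strand six-exon gene reproducing the local structure
#' of the causal locus: codon 203 is CGA (arginine) with its middle base as
#' the last nucleotide of exon 5, so the transcript-sense G>A substitution
#' (genomic C>T, since the gene is on the reverse strand) is simultaneously
#' a missense change (p.Arg203Gln) and a donor splice-region variant. All
#' sequence outside these constraints is synthetic filler - this is NOT the
#' real gene sequence.
#'
#' @return list as from [build_toy_gene()], plus `variant` (the planted
#'   genomic substitution) and `donor_windows` (ref and alt 9-base donor
#'   windows at the exon 5 junction, transcript sense).
#' @export
toy_ataxia_model <- function() {
  n_codons <- 221L # 220 aa + stop
  body <- random_codons(n_codons - 2L, seed = 7L)
  cds <- paste0("ATG", body, "TAA")
  substr(cds, 607L, 609L) <- "CGA" # codon 203: Arg, middle base ends exon 5
  exon_ends <- c(120L, 240L, 360L, 480L, 608L, 3L * n_codons)
  gene <- build_toy_gene(cds, exon_ends, strand = "-", chrom = "chr19",
                         intron_len = 40L, g_start = 27040001L,
                         gene_id = "KIF1C_toy", seed = 11L)
  v <- gene$tx2gen(608L) # transcript G -> genomic C on the reverse strand
  variant <- list(chrom = gene$chrom, pos = v$pos, ref = v$ref, alt = "T")
  ref_win <- paste0(substr(cds, 606L, 608L), "GTAAGT")
  alt_win <- ref_win
  substr(alt_win, 3L, 3L) <- "A"
  c(gene, list(variant = variant,
               donor_windows = list(ref = ref_win, alt = alt_win)))
}
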