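test_that("the packaged reverse-strand model yields p.Arg203Gln + splice_region", {
  m <- toy_ataxia_model()
  expect_equal(m$variant$ref, "C") # genomic sense; transcript sense is G>A
  expect_equal(m$variant$alt, "T")
  cc <- annotate_consequence(m$variant, m$transcript, m$genome)
  expect_setequal(cc$class, c("missense", "splice_region"))
  expect_equal(cc$protein_change, "p.Arg203Gln")
  expect_equal(cc$exon_index, 5L)
  expect_equal(cc$codon_index, 203L)
  expect_equal(cc$ref_codon, "CGA")
  expect_equal(cc$alt_codon, "CAA")
  expect_equal(cc$distance_to_exon_boundary, 0L)
})

test_that("synonymous, intronic and intergenic calls behave", {
  m <- toy_ataxia_model()
  # find a position whose substitution is synonymous (third codon base,
  # fourfold-degenerate site) using the oracle to pick one
  found <- FALSE
  for (i in seq(3, 600, by = 3)) {
    v <- m$tx2gen(i)
    for (alt_tx in setdiff(c("A", "C", "G", "T"), v$base_tx)) {
      if (oracle_classify_substitution(m$cds, i, alt_tx) == "synonymous") {
        valt <- if (m$strand == "-") unname(ataxmap:::COMPLEMENT[alt_tx]) else alt_tx
        cc <- annotate_consequence(list(chrom = m$chrom, pos = v$pos, ref = v$ref,
                                        alt = valt), m$transcript, m$genome)
        expect_true("synonymous" %in% cc$class)
        expect_match(cc$protein_change, "=$")
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  # intronic: one base beyond the donor window of exon 5 (transcript sense)
  ex <- m$transcript$exons
  # reverse strand: intron 5' bases are just below the exon's genomic start
  ex5_start <- sort(ex$start, decreasing = TRUE)[5]
  cci <- annotate_consequence(list(chrom = m$chrom, pos = ex5_start - 10,
                                   ref = "A", alt = "G"), m$transcript, m$genome)
  expect_equal(cci$class, "intronic")
  # intergenic: outside the transcript span
  ccg <- annotate_consequence(list(chrom = m$chrom, pos = 1, ref = "A", alt = "G"),
                              m$transcript, m$genome)
  expect_equal(ccg$class, "intergenic")
})

test_that("every substitution of a 30-codon toy CDS matches the translation oracle (both strands)", {
  # deterministic 30-codon CDS: ATG + 28 codons + stop
  cds <- paste0("ATG", ataxmap:::random_codons(28, seed = 123), "TAA")
  expect_equal(nchar(cds), 90)
  for (strand in c("+", "-")) {
    gene <- build_toy_gene(cds, exon_ends = c(33L, 60L, 90L), strand = strand,
                           chrom = "chrT", g_start = 501L, seed = 5)
    for (i in seq_len(90)) {
      v <- gene$tx2gen(i)
      for (alt_tx in setdiff(c("A", "C", "G", "T"), v$base_tx)) {
        want <- oracle_classify_substitution(cds, i, alt_tx)
        galt <- if (strand == "-") unname(ataxmap:::COMPLEMENT[alt_tx]) else alt_tx
        cc <- annotate_consequence(list(chrom = "chrT", pos = v$pos, ref = v$ref,
                                        alt = galt), gene$transcript, gene$genome)
        got <- setdiff(cc$class, "splice_region")
        expect_equal(got, want,
                     info = sprintf("strand %s, cds pos %d, %s>%s", strand, i,
                                    v$base_tx, alt_tx))
      }
    }
  }
})

test_that("strand involution: the same biology on either strand gives identical protein calls", {
  cds <- paste0("ATG", ataxmap:::random_codons(40, seed = 77), "TGA")
  fwd <- build_toy_gene(cds, exon_ends = c(48L, nchar(cds)), strand = "+", seed = 3)
  rev <- build_toy_gene(cds, exon_ends = c(48L, nchar(cds)), strand = "-", seed = 3)
  set.seed(6)
  for (i in sample(nchar(cds), 25)) {
    vf <- fwd$tx2gen(i); vr <- rev$tx2gen(i)
    for (alt_tx in setdiff(c("A", "C", "G", "T"), vf$base_tx)) {
      cf <- annotate_consequence(list(chrom = "chrT", pos = vf$pos, ref = vf$ref,
                                      alt = alt_tx),
                                 fwd$transcript, fwd$genome)
      cr <- annotate_consequence(list(chrom = "chrT", pos = vr$pos, ref = vr$ref,
                                      alt = unname(ataxmap:::COMPLEMENT[alt_tx])),
                                 rev$transcript, rev$genome)
      expect_equal(cf$protein_change, cr$protein_change)
      expect_setequal(cf$class, cr$class)
    }
  }
})

test_that("indels and model validation", {
  m <- toy_ataxia_model()
  v <- m$tx2gen(300)
  fs <- annotate_consequence(list(chrom = m$chrom, pos = v$pos, ref = paste0(v$ref, "AA"),
                                  alt = v$ref), m$transcript, m$genome)
  expect_true("frameshift" %in% fs$class)
  inf <- annotate_consequence(list(chrom = m$chrom, pos = v$pos,
                                   ref = paste0(v$ref, "AAA"), alt = v$ref),
                              m$transcript, m$genome)
  expect_true("inframe_indel" %in% inf$class)
  # CDS length not divisible by 3 is a model error
  expect_error(transcript_model("bad", "chr1", "+",
                                data.frame(start = 1, end = 10)),
               "divisible by 3")
})
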