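#' Read and write genotype matrices
#'
#' Two on-disk formats are supported, selected by `format`:
#' * `"tsv"`: `<prefix>.geno.tsv` (wide table, `sample_id` then one column
#'   per marker with codes 0/1/2/NA) plus `<prefix>.map.tsv`
#'   (`marker_id`, `chrom`, `pos_bp`).
#' * `"plink"`: `<prefix>.ped` / `<prefix>.map` in PLINK text convention
#'   (alleles coded 1 = reference, 2 = alternate, 0 = missing; map columns
#'   chrom, id, cM, bp).
#'
#' Writing then reading reproduces the in-memory object exactly.
#'
#' @param x a [genotype_matrix()].
#' @param prefix path prefix (extensions appended per format).
#' @param format `"tsv"` or `"plink"`.
#' @return `read_genotypes()` returns a [genotype_matrix()];
#'   `write_genotypes()` returns the written paths invisibly.
#' @export
write_genotypes <- function(x, prefix, format = c("tsv", "plink")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_matrix"))
  if (format == "tsv") {
    geno_path <- paste0(prefix, ".geno.tsv")
    map_path <- paste0(prefix, ".map.tsv")
    dt <- data.table::data.table(sample_id = rownames(x$geno))
    dt <- cbind(dt, data.table::as.data.table(x$geno))
    data.table::fwrite(dt, geno_path, sep = "\t")
    data.table::fwrite(x$map[, c("marker_id", "chrom", "pos_bp")], map_path, sep = "\t")
    return(invisible(c(geno_path, map_path)))
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  g <- x$geno
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  a1[!is.na(g) & g <= 1L] <- "1"; a1[!is.na(g) & g == 2L] <- "2"
  a2[!is.na(g) & g == 0L] <- "1"; a2[!is.na(g) & g >= 1L] <- "2"
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, by = 2L)] <- a1
  inter[, seq(2L, 2L * m, by = 2L)] <- a2
  lead <- cbind(rownames(g), rownames(g), "0", "0", "0", "-9")
  data.table::fwrite(data.table::as.data.table(cbind(lead, inter)), ped_path,
                     sep = " ", col.names = FALSE)
  data.table::fwrite(data.frame(chrom = x$map$chrom, id = x$map$marker_id,
                                cm = 0, bp = x$map$pos_bp),
                     map_path, sep = "\t", col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(prefix, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(paste0(prefix, ".geno.tsv"), sep = "\t")
    map <- as.data.frame(data.table::fread(paste0(prefix, ".map.tsv"), sep = "\t"))
    geno <- as.matrix(dt[, -1L])
    bad <- which(!(geno %in% c(0L, 1L, 2L) | is.na(geno)), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("%s.geno.tsv: invalid genotype code at data row %d",
                   prefix, bad[1L, 1L]), call. = FALSE)
    }
    storage.mode(geno) <- "integer"
    rownames(geno) <- dt[[1L]]
    return(genotype_matrix(geno, map))
  }
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map"), sep = "\t",
                                         header = FALSE,
                                         col.names = c("chrom", "marker_id", "cm", "pos_bp")))
  ped <- data.table::fread(paste0(prefix, ".ped"), sep = " ", header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) {
    stop(sprintf("%s.ped: expected %d columns, found %d", prefix, 6L + 2L * m,
                 ncol(ped)), call. = FALSE)
  }
  a1 <- as.matrix(ped[, seq(7L, 6L + 2L * m, by = 2L), with = FALSE])
  a2 <- as.matrix(ped[, seq(8L, 6L + 2L * m, by = 2L), with = FALSE])
  geno <- (a1 == "2") + (a2 == "2")
  geno[a1 == "0" | a2 == "0"] <- NA
  storage.mode(geno) <- "integer"
  rownames(geno) <- ped[[2L]]
  genotype_matrix(geno, map[, c("marker_id", "chrom", "pos_bp")])
}

#' Read and write pedigree CSV
#'
#' Columns `animal_id, sire_id, dam_id, sex, birth_cohort`; `"0"` encodes an
#' unknown parent.
#'
#' @param ped pedigree `data.frame`; `path` file path.
#' @return `read_pedigree()` returns a validated pedigree `data.frame`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_pedigree
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  ped <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("animal_id", "sire_id", "dam_id"))))
  ped$sire_id[ped$sire_id %in% c("0", "")] <- NA_character_
  ped$dam_id[ped$dam_id %in% c("0", "")] <- NA_character_
  validate_pedigree(ped)
  ped
}

#' Read and write phenotype TSV
#'
#' Long format: `animal_id`, `trait`, `value` (plus any extra columns).
#' @param phen `data.frame`; `path` file path.
#' @export
write_phenotypes <- function(phen, path) {
  data.table::fwrite(phen, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = list(
    character = "animal_id")))
}

#' Write a variant table as VCF v4.2
#'
#' Positions are written 1-based (VCF native, identical to the internal
#' convention - no conversion). Knownness flags go to INFO (`KNOWN`,
#' `ONARRAY`), the consequence to `CSQ`, genotypes to per-sample `GT`.
#'
#' @param variants variant `data.frame` (see [apply_filter_cascade()]).
#' @param path output path.
#' @param sample_ids genotype columns to emit; defaults to every column
#'   whose values are genotype strings.
#' @export
write_vcf <- function(variants, path, sample_ids = NULL) {
  gvals <- c("hom_ref", "het", "hom_alt", "missing")
  if (is.null(sample_ids)) {
    sample_ids <- names(variants)[vapply(variants, function(col) {
      is.character(col) && length(col) > 0 && all(col %in% c(gvals, NA))
    }, logical(1))]
    sample_ids <- setdiff(sample_ids, c("chrom", "ref", "alt", "consequence",
                                        "category", "variant_id"))
  }
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Present in catalogue of known polymorphisms\">",
             "##INFO=<ID=ONARRAY,Number=0,Type=Flag,Description=\"Present on SNP array in other breeds\">",
             "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Predicted consequence\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     "FORMAT", sample_ids), collapse = "\t"))
  for (i in seq_len(nrow(variants))) {
    info <- character(0)
    if (isTRUE(variants$known_in_catalogue[i])) info <- c(info, "KNOWN")
    if (isTRUE(variants$on_array_other_breeds[i])) info <- c(info, "ONARRAY")
    if (!is.null(variants$consequence) && !is.na(variants$consequence[i])) {
      info <- c(info, paste0("CSQ=", variants$consequence[i]))
    }
    info <- if (length(info)) paste(info, collapse = ";") else "."
    gts <- vapply(sample_ids, function(s) {
      g <- variants[[s]][i]
      if (is.na(g)) "./." else gt_code[[g]]
    }, character(1))
    vid <- if (!is.null(variants$variant_id)) variants$variant_id[i] else "."
    lines <- c(lines, paste(c(variants$chrom[i],
                              format(variants$pos[i], scientific = FALSE),
                              vid, variants$ref[i], variants$alt[i], ".", ".",
                              info, "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into the internal variant table
#'
#' Parses with `VariantAnnotation::readVcf()` (positions stay 1-based) and
#' maps GT fields to `hom_ref/het/hom_alt/missing`, INFO flags `KNOWN` /
#' `ONARRAY` to the knownness columns and `CSQ` to `consequence`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return variant `data.frame` as consumed by [apply_filter_cascade()].
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1L], character(1))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    stringsAsFactors = FALSE)
  info <- VariantAnnotation::info(vcf)
  df$known_in_catalogue <- if ("KNOWN" %in% names(info)) info$KNOWN else FALSE
  df$on_array_other_breeds <- if ("ONARRAY" %in% names(info)) info$ONARRAY else FALSE
  if ("CSQ" %in% names(info)) {
    df$consequence <- vapply(info$CSQ, function(x) {
      if (length(x)) as.character(x)[1L] else NA_character_
    }, character(1))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  decode <- function(g) {
    ifelse(g %in% c("./.", ".", ".|."), "missing",
           ifelse(g %in% c("0/0", "0|0"), "hom_ref",
                  ifelse(g %in% c("1/1", "1|1"), "hom_alt", "het")))
  }
  for (s in colnames(gt)) df[[s]] <- decode(gt[, s])
  df$variant_id <- sprintf("%s_%d_%s_%s", df$chrom, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  df
}

#' Write transcript models as GFF3
#'
#' Minimal GFF3 with `gene`, `mRNA`, `exon` and `CDS` features (1-based
#' inclusive coordinates, `Parent` attributes linking the hierarchy).
#'
#' @param transcripts list of [transcript_model()].
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tm in transcripts) {
    gid <- tm$gene_id
    span <- c(min(tm$exons$start), max(tm$exons$end))
    lines <- c(lines,
               sprintf("%s\tataxmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       tm$chrom, span[1], span[2], tm$strand, gid),
               sprintf("%s\tataxmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       tm$chrom, span[1], span[2], tm$strand, gid, gid))
    for (i in seq_len(nrow(tm$exons))) {
      lines <- c(lines, sprintf("%s\tataxmap\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                                tm$chrom, tm$exons$start[i], tm$exons$end[i],
                                tm$strand, gid))
      cs <- max(tm$exons$start[i], tm$cds_start)
      ce <- min(tm$exons$end[i], tm$cds_end)
      if (cs <= ce) {
        lines <- c(lines, sprintf("%s\tataxmap\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s.t1",
                                  tm$chrom, cs, ce, tm$strand, gid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' @param path GFF3 path (exon + CDS features grouped by `Parent`).
#' @return list of [transcript_model()], named by gene id.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type == "mRNA"]
  out <- list()
  for (k in seq_along(mrna)) {
    tid <- mrna$ID[k]
    gid <- sub("\\.t1$", "", tid)
    ex <- gr[gr$type == "exon" &
               vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    cds <- gr[gr$type == "CDS" &
                vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    out[[gid]] <- transcript_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(mrna))[k],
      strand = as.character(GenomicRanges::strand(mrna))[k],
      exons = data.frame(start = GenomicRanges::start(ex),
                         end = GenomicRanges::end(ex)),
      cds_start = min(GenomicRanges::start(cds)),
      cds_end = max(GenomicRanges::end(cds)))
  }
  out
}

#' Write an analysis report
#'
#' Data frames go to TSV; anything else is serialized as JSON.
#' @param object report object.
#' @param path output path.
#' @export
write_report <- function(object, path) {
  if (is.data.frame(object)) {
    data.table::fwrite(object, path, sep = "\t")
  } else {
    jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Machine-readable provenance block
#'
#' Every CLI run records package version, the seed, and an md5 digest of the
#' effective configuration next to its outputs.
#'
#' @param path output JSON path.
#' @param seed seed used for the run.
#' @param config configuration object (any serializable list).
#' @export
write_provenance <- function(path, seed, config = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  jsonlite::write_json(list(
    tool = "ataxmap",
    version = as.character(packageVersion("ataxmap")),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), tz = "UTC")), path, auto_unbox = TRUE)
  invisible(path)
}
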