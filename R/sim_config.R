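#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator, with defaults
#' chosen to emulate the study system: a linebred beef-cattle population with
#' a predominant founder ancestor, a recessive disease haplotype at ~13%
#' carrier frequency, a cohort of ~3300 animals, 46 ascertained cases of
#' which 5 are phenocopies, and a 681-kb causal interval on chromosome 19
#' containing the causal position.
#'
#' @param n_founders number of pedigree founders (>= 2).
#' @param n_generations number of bred generations (>= 2 for a multi-
#'   generation pedigree; 1 is allowed and yields founders only plus one
#'   offspring cohort when > 1).
#' @param n_offspring_per_gen offspring bred per generation.
#' @param target_carrier_frequency desired carrier (heterozygote) frequency of
#'   the planted allele in the bred population; drives the predominant
#'   founder's share of generation-1 matings.
#' @param n_cases_aa number of homozygous-by-descent cases to ascertain.
#' @param n_phenocopies number of affected animals without the causal
#'   genotype (phenocopies) to label among cases.
#' @param n_chromosomes,chrom_length_bp,markers_per_chrom marker map layout:
#'   evenly spaced markers per chromosome. The genome-wide default
#'   (29 x 1724 = ~50k) mirrors a 50K SNP array; chip density inside any
#'   particular interval is a stated guess, not a measured quantity.
#' @param cm_per_mb genetic map density (centimorgan per megabase), uniform.
#' @param founder_freq_range range of founder allele frequencies for neutral
#'   markers (arrays target intermediate frequencies).
#' @param causal_interval a [genomic_interval()] to plant the disease
#'   haplotype on; default chr19:26848700-27529700.
#' @param causal_position 1-based position of the causal variant, inside
#'   `causal_interval`.
#' @param genotype_error per-allele symmetric miscall rate.
#' @param missing_rate per-genotype missingness rate.
#' @param n_background_outside,n_background_genotype,n_background_known,
#'   n_background_array,n_background_nonprotein background variant category
#'   counts for the variant-table simulator (defaults reproduce the shape of
#'   the sequencing filter cascade: 1503 in-interval variants thinning to 1).
#' @param phenotype_sigma_a2,phenotype_sigma_e2 polygenic and residual
#'   variance components for the phenotype simulator (trait units squared).
#' @param seed integer seed; mandatory for every stochastic operation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20L,
                       n_generations = 10L,
                       n_offspring_per_gen = 360L,
                       target_carrier_frequency = 0.13,
                       n_cases_aa = 41L,
                       n_phenocopies = 5L,
                       n_chromosomes = 29L,
                       chrom_length_bp = 1e8,
                       markers_per_chrom = 1724L,
                       cm_per_mb = 1,
                       founder_freq_range = c(0.1, 0.9),
                       causal_interval = genomic_interval("chr19", 26848700, 27529700),
                       causal_position = 27041449,
                       genotype_error = 0.001,
                       missing_rate = 0.01,
                       n_background_outside = 500L,
                       n_background_genotype = 1136L,
                       n_background_known = 208L,
                       n_background_array = 13L,
                       n_background_nonprotein = 145L,
                       phenotype_sigma_a2 = 0.3 * 9.4^2,
                       phenotype_sigma_e2 = 0.7 * 9.4^2,
                       seed = 1L) {
  n_founders <- assert_count(n_founders, "n_founders", min = 2L)
  n_generations <- assert_count(n_generations, "n_generations", min = 1L)
  n_offspring_per_gen <- assert_count(n_offspring_per_gen, "n_offspring_per_gen", min = 1L)
  assert_prob(target_carrier_frequency, "target_carrier_frequency")
  n_cases_aa <- assert_count(n_cases_aa, "n_cases_aa")
  n_phenocopies <- assert_count(n_phenocopies, "n_phenocopies")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", min = 1L)
  markers_per_chrom <- assert_count(markers_per_chrom, "markers_per_chrom", min = 2L)
  assert_prob(genotype_error, "genotype_error")
  assert_prob(missing_rate, "missing_rate")
  if (!inherits(causal_interval, "genomic_interval")) {
    stop("configuration error: `causal_interval` must be a genomic_interval",
         call. = FALSE)
  }
  if (causal_position < causal_interval$start || causal_position > causal_interval$end) {
    stop("configuration error: `causal_position` must lie inside `causal_interval`",
         call. = FALSE)
  }
  if (cm_per_mb <= 0) stop("configuration error: `cm_per_mb` must be positive", call. = FALSE)
  if (phenotype_sigma_a2 < 0 || phenotype_sigma_e2 < 0) {
    stop("configuration error: variance components must be non-negative", call. = FALSE)
  }
  seed <- assert_count(seed, "seed")
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    n_offspring_per_gen = n_offspring_per_gen,
    target_carrier_frequency = target_carrier_frequency,
    n_cases_aa = n_cases_aa, n_phenocopies = n_phenocopies,
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    markers_per_chrom = markers_per_chrom, cm_per_mb = cm_per_mb,
    founder_freq_range = founder_freq_range,
    causal_interval = causal_interval, causal_position = causal_position,
    genotype_error = genotype_error, missing_rate = missing_rate,
    n_background_outside = n_background_outside,
    n_background_genotype = n_background_genotype,
    n_background_known = n_background_known,
    n_background_array = n_background_array,
    n_background_nonprotein = n_background_nonprotein,
    phenotype_sigma_a2 = phenotype_sigma_a2,
    phenotype_sigma_e2 = phenotype_sigma_e2,
    seed = seed), class = "sim_config")
}

#' Evenly spaced marker map under a configuration
#'
#' Chromosomes are labelled `chr1..chrN`; markers are evenly spaced along
#' each chromosome; genetic positions follow a uniform `cm_per_mb` map.
#'
#' @param config a [sim_config()].
#' @return `data.frame` with `marker_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   sorted by chromosome then position.
#' @export
marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per <- config$markers_per_chrom
  step <- config$chrom_length_bp / per
  maps <- lapply(seq_len(config$n_chromosomes), function(ci) {
    pos <- round(step * (seq_len(per) - 0.5))
    data.frame(marker_id = sprintf("chr%d_m%04d", ci, seq_len(per)),
               chrom = sprintf("chr%d", ci), pos_bp = pos,
               pos_cm = pos / 1e6 * config$cm_per_mb)
  })
  do.call(rbind, maps)
}
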