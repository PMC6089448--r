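---
title: "Methods: autozygosity mapping and characterization of a recessive bovine variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autozygosity mapping and characterization of a recessive bovine variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ataxmap` implements the inference chain by which a recessive Mendelian
disease in a livestock population is mapped from SNP-array genotypes to a
single causal substitution and characterized: shared-autozygosity interval
mapping, a case/control variant filtering cascade with coding-consequence
annotation and splice donor scoring, cohort allele-frequency statistics, a
pedigree mixed-model genotype-trait association, and morphometry of
paranodal immunostaining lengths. A synthetic-data generator with a full
ground-truth ledger stands in for the study animals, so that every step of
the chain can be validated by recovery of planted truth.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic world does and does not establish.

## The disease model and the synthetic world

The motivating system is a progressive ataxia segregating recessively in a
beef breed: a single founder bull (born in the 1960s) carries one copy of a
causal allele; decades of linebreeding raise the carrier frequency to about
13%, and affected animals are homozygous by descent for the founder
haplotype around the causal locus. Case series accumulate over many years
through a national disease observatory, and a minority of recorded cases
(5 of 46 here) are phenocopies — clinically similar animals without the
causal genotype.

`sim_config()` states this world explicitly:

* **Pedigree** (`simulate_pedigree`): founders form generation 0; the first
  male founder is the predominant ancestor. His share of generation-1
  matings is derived from the target carrier frequency: with allele
  frequency $q$ solving $2q(1-q) = 0.13$, his expected genomic contribution
  must be $2q \approx 0.14$, i.e. a generation-1 siring share of $4q$.
  Later generations mate uniformly within the previous generation, which
  preserves expected founder contributions (a martingale argument) while
  letting them drift realistically. The default depth is **10 generations**:
  the real founder-to-case span (1964 to the 2000s) is 8-10 bovine
  generations, and depth is not a free parameter — with few meioses between
  founder and cases the shared identical-by-descent segments span tens of
  megabases and no sub-megabase minimal interval exists to be mapped.
* **Genotypes** (`gene_drop`): founder haplotypes are independent draws at
  per-marker allele frequencies uniform on (0.1, 0.9) (arrays target
  intermediate frequencies); transmission applies crossovers as a Poisson
  process on a uniform 1 cM/Mb genetic map (the study gives no map).
  Default marker map: 29 chromosomes x 1724 evenly spaced markers, a 50K
  array; the informative density inside any particular interval is a stated
  guess, not a measurement. A symmetric per-allele miscall layer (0.001)
  and missingness (0.01) are applied last, so Mendelian consistency holds
  for the raw haplotypes.
* **Cases**: naturally arising homozygotes are supplemented by offspring of
  carrier-by-carrier matings sampled from the pedigree until 41 homozygous
  cases exist — emulating ascertainment of a rare recessive from a national
  population (every case's parents are carriers, as observed in the study
  system). Five phenocopies are then labelled among animals that do **not**
  bear the founder haplotype on the causal chromosome (no homozygous
  state-identical tract of 6+ consecutive loci), mirroring the reported
  property that phenocopy cases did not carry the mapped haplotype.
* **Phenotypes** (`simulate_phenotypes`): $y = \mu + X\beta + u + e$ with
  $u \sim N(0, A\sigma_a^2)$ realized through the Cholesky factor of the
  pedigree relationship matrix and $e \sim N(0, I\sigma_e^2)$. Defaults put
  30% of a phenotypic variance of $9.4^2$ (the muscular-development score
  scale) into the polygenic term. Phenotypes are emitted pre-corrected —
  environmental effects are assumed removed upstream, as in national
  genetic evaluations; an additive nuisance layer exists for stress testing
  and defaults off.
* **Morphometry** (`simulate_paranodal_lengths`): paranodal immunostaining
  lengths are strictly positive and right-skewed (reported ranges reach
  about 39 um against means of 2-16 um), so groups are drawn from
  log-normal distributions moment-matched to the target mean and SD
  (`lognormal_params`); no distribution is stated in the source system, and
  the reported dispersions are used as the generator's target SDs. If they
  are standard errors rather than SDs the true spread is larger, which
  affects none of the qualitative conclusions and only weakens the (still
  overwhelming) group separation.

What a green recovery test establishes: that the mapping, filtering and
association machinery recovers planted truth under this stated world. What
it does not establish: performance under real linkage-disequilibrium
backgrounds (founder haplotypes here are exchangeable Bernoulli mosaics),
under non-uniform genetic maps, or under ascertainment schemes other than
the carrier-mating top-up.

## Runs of homozygosity and the shared interval

`detect_roh()` reports maximal marker runs per animal in which
heterozygous calls and missing calls stay within configured tolerances,
trimmed to homozygous endpoints. The defaults are calibrated jointly for
50K density and megabase-scale autozygous segments:

| parameter | default | rationale |
|---|---|---|
| `min_markers` | 15 | ~750 kb at 50-kb spacing; chance homozygosity-by-state runs of this length are vanishingly rare (~$0.55^{15}$ per position) |
| `min_length_bp` | 500 kb | shortest credible autozygous segment at array resolution |
| `max_het_calls` | 3 | at a 0.1% allele miscall rate a 200-marker segment shows ~0.4 spurious hets; a tolerance of 1 fragments true segments |
| `max_missing_calls` | 10 | at 1% missingness a 200-marker segment exceeds 2 missing calls ~30% of the time; absent calls carry no evidence against homozygosity |

`min_markers` and `min_length_bp` are deliberately consistent with each
other at array density: a marker minimum of 20 (about 1 Mb) silently
over-rides a 500-kb length threshold and discards true 800-kb shared
tracts, which measurably breaks interval recovery.

`map_shared_interval()` performs the mapping: every marker covered by
segments from at least `min_case_fraction` of cases (default 0.85; the
observed case series had 41/46 ≈ 0.89) anchors a candidate. Support at an
anchor is the set of cases whose segment covers it; the candidate interval
is the intersection of their segments. The decisive refinement is the
**haplotype analysis**: supporting cases must be homozygous for a shared
consensus haplotype across the interval. A case contradicting the
per-marker majority homozygous allele — counting both mismatching
homozygous calls and heterozygous calls — at more than
`max(max_discord_markers, ceiling(max_discord_fraction * informative))`
positions is moved to the discordant set and the intersection is
recomputed. Without this step the method is not usable in a linebred
population: flanking regions where all homozygous-by-descent cases still
share the founder segment, plus one chance-consistent extra animal,
outrank the causal constriction. The discordance tolerance (default 10% of
informative markers, floor 1) separates two regimes cleanly: a truly
shared haplotype mismatches only through double miscalls (~$10^{-6}$ per
marker), while a different autozygous haplotype mismatches at roughly half
of informative markers; values much below 10% over-drop cases whose own
autozygosity extends past the shared segment, and values much above it
re-admit state-matching flukes.

Candidates are deduplicated across anchors, required to span
`min_length_bp`, and ranked by supporting-case count, then marker count,
then length. Coordinates are 1-based inclusive with endpoints at marker
positions (no extrapolation beyond flanking markers); interval length is
defined as `end - start`, the convention under which the published bounds
26,848,700-27,529,700 give exactly 681 kb. BED export (0-based half-open)
subtracts 1 from the start only.

## The variant filtering cascade

`apply_filter_cascade()` applies, in order: (1) restriction to the mapped
interval; (2) segregation — homozygous alternate in all affected,
not homozygous alternate in the controls (a missing call in a case fails
the criterion, conservatively; with several controls the default requires
all of them to lack the homozygous-alternate genotype, switchable to
`any`); (3) exclusion of catalogued polymorphisms; (4) exclusion of array
content from other breeds; (5) retention of protein-altering classes
(missense, stop gain/loss, start loss, frameshift). Counts are monotone
non-increasing and every dropped variant is attributed to its first
failing step.

Because the candidate of interest is simultaneously missense and
splice-disrupting, a purely synonymous exon-terminal variant would be
discarded by step 5 even if it destroyed the donor site;
`keep_splice_synonymous` retains synonymous donor splice-region variants
whose PWM score drop exceeds a threshold (default 1 bit).

`annotate_consequence()` locates a variant in a minimal transcript model,
translates affected codons with the standard genetic code (reverse-strand
transcripts complement the alleles and reverse exon order before codon
lookup), and adds a multi-label `splice_region` flag for the donor window
(last 3 exonic / first 6 intronic bases of each non-terminal exon; an
acceptor window is available but off by default, as the variant of
interest is donor-side). Indels are classified minimally by length modulo
3. The packaged `toy_ataxia_model()` reproduces the local structure of the
real locus — a reverse-strand gene whose codon 203 (CGA, arginine) has its
middle base as the last nucleotide of exon 5, so the transcript-sense G>A
(genomic C>T) substitution yields `missense + splice_region`,
p.Arg203Gln — with all other sequence synthetic filler.

`score_donor_site()` is a generic 9-base donor position-weight-matrix
scorer, $\sum_i \log_2 (p_i(b_i)/0.25)$. The packaged matrix is built from
the canonical mammalian donor consensus (CAG|GTAAGT, the invariant GT
smoothed to 0.997 to keep scores finite). It is **not** the matrix of any
external scoring server, so published absolute scores are out of scope;
only score differences between reference and alternate windows are
meaningful, and the packaged model's exon-5 G>A gives a drop of about 3.3
bits, qualitatively matching the published weakening.

## Cohort statistics

`allele_frequency()` and `homozygote_fraction()` implement the cohort
arithmetic with both printing conventions (one-decimal table style and
integer-percent prose style; ties round half away from zero, matching the
printed tables). `effect_ratios()` expresses a genotype contrast relative
to the phenotypic mean (percent, one decimal) and SD (two decimals).
`homozygote_deficit_test()` is a conditional exact one-sided
Hardy-Weinberg test (Levene distribution of the homozygote count given
allele counts) — exact rather than chi-square because the cohorts of
interest have empty homozygote cells at older ages, exactly the pattern of
a recessive condition removing homozygotes. `frequency_trajectory()`
applies the frequency estimate across age cohorts and flags a monotone
decline of the integer-percent sequence when present; in the published
table the 24-month cohort breaks strict monotonicity, so the flag is
deliberately conservative.

## The mixed-model association

`build_numerator_relationship()` constructs A by the recursive tabular
method (diagonal $1 + F_i$; unknown parents are unrelated, non-inbred
founders) and verifies positive semi-definiteness by attempted Cholesky
factorization on every build. `relationship_inverse()` provides the sparse
Henderson inverse with inbreeding-adjusted Mendelian sampling variances;
`solve_mme()` uses it in Henderson's mixed-model equations and is
contracted to agree with the dense generalized-least-squares route inside
`reml_fit()` to about 1e-8 at the same variance ratio.

`reml_fit()` maximizes the restricted likelihood of
$y = 1\mu + X\beta + u + e$ with the genotype coded as a 3-level class (GG
baseline — the reported quantities are class contrasts, not an additive
dosage effect). Numerically, an eigendecomposition of A rotates the model
so each likelihood evaluation is a diagonal weighted least squares;
Brent's method searches the log variance ratio on $[10^{-4}, 10^4]$ with
tolerance $10^{-6}$, and endpoint candidates guard against boundary
optima. Reusing the eigendecomposition across replicate fits makes
simulation studies (100 fits at n = 3000; 1000 fits at n = 500) cheap.
Inference on contrasts is Wald-z; outputs note that small-cohort p-values
(n ≈ 250 at 30 months in the motivating data) are approximate. A genotype
class with no phenotyped animals yields a non-estimable contrast with a
reason, not an error — the 30-month cohorts genuinely contain no
homozygotes. No multiple-testing correction is applied to the significance
stars (matching the nominal-p presentation of the source tables); a
Bonferroni column is emitted for transparency.

## Morphometry

`summarize_groups()` reports n, mean, standard error and range per group
(SE undefined at n = 1 and reported missing). `anova_oneway()` is the
classical one-way fixed-effects decomposition on raw lengths, as the
source analysis used; a log-scale option exists because lengths are
right-skewed but defaults off to match. Degenerate inputs (zero
within-group variance) yield an infinite F with a warning rather than an
error. No post-hoc pairwise correction is applied by default.

## Input and output conventions

Internal coordinates are 1-based inclusive everywhere (VCF-native); BED is
conversion-on-export only. Genotypes round-trip through a wide TSV pair or
PLINK-style `.ped`/`.map` text; variants through VCF v4.2 (knownness flags
as INFO flags, consequences as `CSQ`); transcripts through minimal GFF3;
pedigrees through CSV with `"0"` for unknown parents. Every CLI run
(`ataxmap simulate|roh|filter|freq|assoc|morpho`) writes a provenance JSON
(package version, seed, configuration digest). Run configuration files are
JSON with unknown keys rejected.

## Known limitations

* Founder haplotypes are exchangeable Bernoulli mosaics: no realistic
  linkage disequilibrium beyond what gene dropping creates, and no
  ascertainment of array markers by polymorphism in the simulated breed.
* The consequence annotator handles single transcripts with
  CDS-spanning exons and minimal indel logic; it is not a general
  VEP-style annotator across transcript sets.
* The donor PWM is a consensus model; absolute scores are not comparable
  with any external server's output.
* Wald inference on REML contrasts is asymptotic; no Kenward-Roger-style
  small-sample correction is attempted.
* The exact thresholds of the original in-house homozygosity-mapping
  software are unpublished; the defaults here are calibrated on the
  synthetic world (calibration documented above) and exposed as
  parameters, not claimed to reproduce that software.
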