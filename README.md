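# ataxmap

Mapping a recessive Mendelian disease in livestock from SNP-array data to a
single causal variant — and characterizing it — as a tested, reusable R
pipeline. The package is aimed at quantitative/statistical geneticists
working on monogenic defects in pedigreed populations (cattle breeds in
particular) and at anyone who wants a fully synthetic, ground-truthed
test-bed for autozygosity mapping.

The core inference chain:

1. **Shared-autozygosity interval mapping.** Cases of a recessive disease
   descending from one founder are homozygous by descent for the founder
   haplotype around the causal locus. `detect_roh()` finds runs of
   homozygosity per animal; `map_shared_interval()` finds the interval
   where at least a fraction `min_case_fraction` of cases (default 0.85 —
   phenocopy tolerance) carry overlapping runs homozygous for the **same**
   consensus haplotype, and reports the minimal common interval
   (intersection over supporting cases), with discordant cases listed.
2. **Variant filtering.** `apply_filter_cascade()` prioritizes sequencing
   variants in the mapped interval: homozygous-alternate in all affected /
   not in controls, absent from the known-polymorphism catalogue and from
   array content of other breeds, protein-altering. A bespoke annotator
   (`annotate_consequence()`, reverse-strand aware, donor splice-region
   flagging) and a splice donor PWM scorer (`score_donor_site()`) support
   the last step.
3. **Cohort statistics.** `allele_frequency()`, `homozygote_fraction()`,
   `effect_ratios()`, an exact conditional homozygote-deficit test, and
   age-cohort frequency trajectories.
4. **Association.** Pedigree numerator relationship matrix (tabular method
   and sparse Henderson inverse) and a REML animal model
   `y = 1μ + Xβ + u + e`, `u ~ N(0, A σ²ₐ)`, with genotype as a 3-level
   class and Wald contrasts AG−GG / AA−GG (`reml_fit()`,
   `genotype_contrasts()`).
5. **Morphometry.** Group summaries and one-way ANOVA for paranodal
   immunostaining lengths (`summarize_groups()`, `anova_oneway()`).
6. **Synthetic data with ground truth.** `simulate_pedigree()` (linebred,
   predominant founder), `gene_drop()` (recombination on a genetic map,
   planted disease haplotype, ascertained cases and phenocopies),
   `simulate_variant_table()`, `simulate_phenotypes()`,
   `simulate_paranodal_lengths()` — every generator records truth for
   recovery testing.

See `vignettes/ataxmap-methods.Rmd` for the models, parameter rationale
and limitations.

## Worked example

```r
library(ataxmap)

# cohort arithmetic: 2698 GG / 854 AG / 45 AA genotyped animals
cc <- cohort_counts(2698, 854, 45, label = "Charolais")
allele_frequency(cc)$percent_int
#> [1] 13

# deficit of homozygotes in a 30-month cohort with zero AA animals
h <- homozygote_deficit_test(cohort_counts(189, 60, 0))
round(h$expected_AA, 1); signif(h$p_value, 3)
#> [1] 3.6
#> [1] 0.0174    # one-sided exact: ~3.6 AA expected under HWE, none seen

# the packaged toy locus: reverse-strand gene, codon 203 = CGA with its
# middle base ending exon 5; the genomic C>T is transcript-sense G>A
m <- toy_ataxia_model()
annotate_consequence(m$variant, m$transcript, m$genome)
#> <consequence_call> missense+splice_region p.Arg203Gln exon 5, codon 203 CGA>CAA

# the same substitution weakens the donor site under the packaged PWM
d <- score_donor_delta(m$donor_windows$ref, m$donor_windows$alt)
sprintf("%.2f -> %.2f (delta %.2f bits)", d$ref, d$alt, d$delta)
#> [1] "10.48 -> 7.14 (delta -3.34 bits)"
```

A full simulate → map → filter → associate run is exercised end-to-end in
`tests/testthat/test-cli.R`; the command-line entry point is

```sh
ataxmap simulate --config config.json --out simdir
ataxmap roh    --geno simdir/genotypes --cases cases.txt --out rohdir
ataxmap filter --vcf simdir/variants.vcf --interval chr19:26848700-27529700 \
               --cases CASE_SEQ1,CASE_SEQ2 --controls CTRL_SEQ1 --out filtdir
ataxmap freq   --counts counts.tsv --out freqdir
ataxmap assoc  --pedigree simdir/pedigree.csv --phenotypes simdir/phenotypes.tsv \
               --genotypes classes.tsv --out assocdir
ataxmap morpho --measures simdir/paranodal_lengths.tsv --out morphodir
```

(`exec/ataxmap` is installed with the package; equivalently call
`ataxmap::ataxmap_cli(c("simulate", ...))`.)

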