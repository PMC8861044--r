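# autozyg

Homozygosity mapping and variant prioritization for whole-genome sequencing
of families with recent shared ancestry.

## The problem

In offspring of consanguineous unions, long stretches of the genome are
inherited identical by descent through both parents. These autozygous
segments appear in sequencing data as runs of homozygosity (ROHs), and they
expose rare recessive alleles in the homozygous state — alleles that would
almost never be observed homozygous in outbred cohorts. Family studies of
heterogeneous neurodevelopmental conditions exploit this: map each affected
child's ROHs, filter variants under explicit inheritance models, annotate
the noncoding remainder against brain regulatory elements, and prioritize
candidates by damage prediction and known-gene evidence.

`autozyg` implements that pipeline end to end for analysts working with
such cohorts, plus a synthetic-cohort generator so every stage can be
validated against known truth without protected patient data:

* **Simulation** — `build_pedigree()`, `gene_drop()`, `synthesize_sites()`,
  `plant_variants()`, `write_fixture_bundle()`: consanguineous pedigrees,
  gene dropping with Poisson recombination (uniform 1 cM/Mb map), truth
  autozygosity segments, planted de novo / compound-het / homozygous-in-ROH
  / X-linked candidates, and a complete VCF + pedigree + BED + gene-table
  input bundle.
* **Variant core** — `read_cohort_vcf()` (multi-allelic decomposition),
  `qc_pass()` (PASS, GQ ≥ 99, allelic depth ≥ 10), `classify_frequency()`
  (rare < 1% in 1000G/gnomAD/GME; ultra-rare = 0 in all three; private).
* **Inheritance models** — `call_de_novo()` (allele balance 0.3–0.7, or
  ≥ 0.7 on the male X; QD ≥ 4; ReadPosRankSum ≥ −2.5; AF < 0.1%; indel
  < 50 bp; repeat exclusion; no other cohort carrier),
  `call_compound_het()`, `call_hom_inherited()`, `call_x_linked()`.
* **ROH** — `roh_site_filter()` (HWE exact p ≥ 0.001, MAF > 5%,
  missingness ≤ 25%), `detect_roh()` (100-variant sliding windows, ≤ 30
  het and ≤ 30 missing per window, PHOM ≥ 0.75, segments > 1 Mb),
  `roh_metrics()`, `merge_shared_roh()`, `subtract_parental_roh()`,
  `variants_in_roh()`.
* **Regulatory annotation** — `classify_promoter()` / `classify_enhancer()`
  (brain H3K4me3 peaks and predicted regulatory elements, with
  brain-specificity against nine non-neuronal chromatin-state tracks),
  `link_to_genes()` via promoter–enhancer interaction pairs,
  `annotate_roh_noncoding()`.
* **Burden** — `classify_effect()` (ND / MD / LoF; MD = nonsynonymous with
  ≥ 2 of SIFT < 0.05, PolyPhen-2 HumVar > 0.15, PROVEAN < −2.5,
  MutationAssessor > 2.26), `roh_burden_rates()` (variants per 10⁸ bp
  inside vs outside ROHs), `hom_fraction_in_roh()`,
  `constraint_comparison()` (pLI/pRec/pNull), `group_burden()`.
* **Prioritization** — `candidate_filter()`, `subpop_deprioritize()`,
  `cross_reference()`, `cnv_overlap_filter()`, `assign_tier()` with an
  auditable rationale vector and `select_candidates()` per-sample reports.

The central quantitative anchor: the expected autozygous genome fraction of
a child equals the kinship of its parents — **6.25%** for first-cousin and
**12.5%** for double-first-cousin offspring — and both the simulator's truth
segments and the ROH caller recover these expectations at cohort scale.

## Worked example

Simulate one first-cousin family on the ~300 Mb test genome, plant a de novo
stopgain and an inherited homozygous variant inside an autozygous segment,
then run the callers and the ROH detector:

```r
library(autozyg)

model <- default_genome("test", site_density = 20)
ped <- build_pedigree("first_cousin", n_children = 1)
co <- sim_cohort(ped, model, seed = 33, plant = list(
  plant_spec("de_novo", "FAM1_c1", known_gene = TRUE),
  plant_spec("hom_in_roh", "FAM1_c1")))

vt <- as_variant_table(co)
dn <- call_de_novo(vt, co$pedigree, "FAM1_c1", model = model)
dn[dn$call, c("site_id", "allele_balance")]
#> # A tibble: 1 x 2
#>   site_id allele_balance
#> 1 p1                0.52

auto <- co$sites$chrom != "chrX"
keep <- roh_site_filter(co$geno[auto, ])
segs <- detect_roh(co$geno[auto, "FAM1_c1"][keep],
                   co$sites[auto, ][keep, ], sample_id = "FAM1_c1")
segs[, c("chrom", "start", "end", "n_sites", "phom")]
#> # A tibble: 1 x 5
#>   chrom start      end n_sites  phom
#> 1 chr14 95296 10940140     171     1
roh_metrics(segs, autosome_length(model))
#> # A tibble: 1 x 5
#>   n_segments mean_length_bp max_length_bp total_length_bp genome_fraction
#> 1          1       10844845      10844845        10844845          0.0361
```

The de novo caller recovers exactly the planted event `p1` (allele balance
0.52, inside the 0.3–0.7 acceptance window, with both parents
homozygous-reference). The detector calls one ROH spanning most of chr14
with PHOM = 1; it contains the planted homozygous variant `p2`, and the
per-genome homozygous fraction (3.6% for this child) is one draw from a
distribution whose mean across many first-cousin children is 6.25%. The
truth ledger `co$ledger` records every planted event for comparison.

## Documentation

The methods vignette (`vignettes/homozygosity-mapping.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
numerical choices (window semantics, segment-edge refinement, degenerate
inputs).
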