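---
title: "Homozygosity mapping and variant prioritization in consanguineous families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping and variant prioritization in consanguineous families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The analysis problem

Offspring of consanguineous unions inherit long genomic segments that are
identical by descent through both parents (autozygous segments), visible in
sequencing data as runs of homozygosity (ROHs). Rare recessive disease
alleles that would almost never be observed homozygous in outbred
populations are exposed inside these segments, which makes family cohorts
with recent shared ancestry a powerful design for recessive gene discovery
in heterogeneous conditions such as autism spectrum disorder.

`autozyg` implements the full downstream analysis for such cohorts —
genotype QC and frequency classification, inheritance-model variant calling,
ROH detection and cross-proband comparison, regulatory annotation of
noncoding variants, burden statistics, and candidate prioritization —
together with a synthetic cohort generator that makes every stage testable
against known truth without access to protected patient data.

## The synthetic cohort generator

### Pedigrees and gene dropping

`build_pedigree()` constructs trio, first-cousin, and double-first-cousin
families with every ancestor needed for simulation materialized as a
founder. The focal parents of a first-cousin family share one grandparental
couple (kinship $\varphi = 1/16$); double first cousins share both couples
($\varphi = 1/8$). The inbreeding coefficient of a child equals the kinship
of its parents, so the expected autozygous genome fraction is **6.25%** for
first-cousin offspring and **12.5%** for double-first-cousin offspring —
the two analytic anchors the simulator must reproduce.

`gene_drop()` labels each founder chromosome uniquely and transmits
recombinant mosaics down the pedigree. The genetic map is uniform at
1 cM/Mb with no crossover interference, so crossover counts per meiosis are
Poisson(length~Mb~ $\times$ rate / 100); uniformity keeps the analytic
expectations exact and is the conventional desk-scale simplification when no
empirical map is modeled. Truth output records, per child, the maximal
autosomal intervals where both haplotypes descend from the same founder
chromosome, and the crossover count of every meiosis.

The X chromosome is transmitted hemizygously to males outside the
pseudoautosomal regions (PARs): a male carries one full maternal X plus a
paternal PAR-only haplotype, and a female receives her father's X intact.
PARs are transmitted without crossover — a deliberate simplification; the
pipeline only needs PAR positions to be diploid in males so the
pseudoautosomal exclusion rule of X-linked calling is exercised. PAR
coordinates default to the GRCh37 convention rescaled to the model's X.

### Sites, genotypes, and planted candidates

`synthesize_sites()` draws variant positions at a configurable density
(default 100/Mb, matching a generous post-filter WGS site panel) and assigns
each site a founder allele frequency from `af_spec`: by default 90% common
sites (AF uniform on 0.1–0.5) and 10% rare sites (AF 0.0005–0.005). The
three population-database frequencies (1000G, gnomAD, GME) are stamped
concordantly with the site's class; a concordance parameter below 1 makes
one database discordant so the "rare in all three" rule is testable. Genes
are modeled as 100 kb bins. Two genome profiles ship as defaults: a ~300 Mb
"test" genome for unit tests and a ~2,700 Mb 22-autosome "full" profile
(lengths proportional to GRCh37) for the cohort-scale autozygosity
experiments.

`plant_variants()` stamps candidate events with genotype configurations
matching their inheritance definitions (de novo: child-only allele with
in-range allele balance, QD and ReadPosRankSum; compound het: one
paternally-only and one maternally-only transmitted heterozygote in one
gene; inherited homozygous: child homozygous, parents heterozygous, located
inside a truth autozygous segment of at least 1 Mb; X-linked: hemizygous
male child, carrier mother, non-carrier father), records every event in a
truth ledger, and can request regulatory track overlap so the noncoding
annotation stage has planted positives. `write_fixture_bundle()` emits the
complete input file set — VCF v4.2 with `GT:GQ:AD` genotypes and annotation
INFO keys, pedigree TSV, BED tracks (0-based half-open on disk; all in-memory
intervals are 1-based inclusive), interaction pairs, and gene tables — and
everything round-trips through the package readers.

What the generator does *not* emulate: read-level errors (GQ/AD are stamped,
not sampled from a noise model), linkage disequilibrium among founder
haplotypes, mutation-rate realism, and population structure. Tests passing
on these fixtures therefore demonstrate the correctness of the pipeline's
logic and its recovery of planted signal under clean conditions, not its
robustness to real-world genotyping noise.

## Variant filtering and inheritance models

Genotype QC requires FILTER `PASS`, GQ $\ge$ 99, and called-allele depth
$\ge$ 10. The depth rule is applied to the alternate-supporting reads for
alternate-carrying genotypes (reference reads for reference calls) — the
conservative reading of an "allelic read depth" filter; a total-depth mode
is available (`depth_mode = "total"`). Filtering is per genotype: a site
may pass in one sample and fail in another.

Frequency classes: *rare* = AF < 1% in all three databases; *ultra-rare* =
AF 0 (or absent) in all three; *private* = ultra-rare and carried by a
single cohort individual. Absent database frequencies are treated as 0
(variant unobserved) with an `observed` flag preserving the distinction.

De novo calls require the child to carry an allele absent from father,
mother, and sibling (when present), plus: allele balance in [0.3, 0.7]
(or $\ge$ 0.7 for X/Y sites in males), QD $\ge$ 4, ReadPosRankSum $\ge$
−2.5, AF < 0.1% in all three databases, no other cohort carrier, indel
length < 50 bp, and location outside segmental duplications and simple
repeats. Sites with a missing genotype in a required individual are
disqualified for that mode and reported with a reason rather than silently
dropped — no imputation is attempted. Compound heterozygotes are paired by
transmission phase only (one parent heterozygous, the other a non-carrier);
sites heterozygous in both parents are phase-ambiguous without read-backed
phasing and are excluded. Inherited homozygous calls require het $\times$
het parents (full-penetrance assumption excludes homozygous parents) and are
vetoed by a homozygous unaffected sibling. X-linked recessive calls require
a hemizygous male child, heterozygous mother, and non-carrier father, with
pseudoautosomal sites heterozygous in the child excluded.

## ROH detection

Sites are first filtered at the cohort level: Hardy-Weinberg exact test
p $\ge$ 0.001, minor allele frequency > 5%, missingness $\le$ 25%. The HWE
test is the exact conditional test on genotype counts, two-sided by summing
all configurations no more probable than the observed one, computed by the
standard stable recurrence; the unit tests verify it against an independent
log-factorial enumeration to below 1e−9.

Detection is a sliding-window scan: windows of 100 *variants* qualify when
they contain at most 30 heterozygous and 30 missing genotypes; sites covered
by a qualifying window form candidate runs; a run is emitted when its
fraction of homozygous calls among non-missing calls (PHOM) is at least
0.75 and it exceeds 1 Mb. The window unit deserves emphasis: the length is
in variants, not base pairs — 30 heterozygotes within 100 bp is not a
satisfiable configuration at WGS site density, so a literal base-pair
reading of the window would be vacuous. All parameters are exposed
(`window_sites`, `max_het`, `max_missing`, `phom`, `min_length_bp`), and
alternative PHOM thresholds (50/70/80%) are a parameter away.

Two boundary decisions matter for fidelity against truth segments:

* **Trimming.** Emitted boundaries are the first and last homozygous sites
  of the run, so segment length is never inflated into unobserved flanks.
* **Edge refinement.** The 30-het window allowance is permissive enough
  that a run can extend tens of sites into flanking heterozygote-dense
  sequence before a window finally disqualifies. Each end is therefore
  trimmed inward to the outermost homozygous site whose inward-facing
  30-site window itself meets the PHOM threshold (at most
  `floor((1 − phom) × 30)` heterozygotes). In simulation this moves the
  called-versus-truth Jaccard overlap from ~0.93 to ~0.98 at 100 sites/Mb
  without biasing length on genuinely homozygous runs; `edge_sites = 0`
  disables it.

Per-genome metrics use autosomal segments only; the genome fraction divides
total ROH length by a callable-bases denominator (the simulated genome
length for synthetic data; for real data, pass the bases sequenced at 1×).
Segments shared by at least two affected individuals are merged by
single-linkage chaining of overlaps into union intervals with carrier
counts, and child segments overlapping any parental ROH can be subtracted
(any-overlap semantics: one shared base removes the child segment).

### Calibration of the recovery experiments

`simulate_autozygosity_study()` reproduces the two analytic expectations at
full scale: 100 replicate children per union type, simulated as 25
independent families of four so that the empirical standard error over
children is an honest estimate of spread. One calibration detail: the site
filter is applied **within each family**. Founder allele content is drawn
per family, so a site that is polymorphic in the population can be
monomorphic among one family's founders; filtering on the pooled
multi-family cohort retains such family-uninformative sites and inflates
that family's detected homozygosity-by-state (about +0.5 percentage points
in our measurements), whereas per-family filtering recovers the analytic
expectation without detectable bias. On real single-cohort data the
distinction does not arise in this form, but the same mechanism — cohort
polymorphism does not imply within-family informativeness — is one reason
observed cohort homozygosity exceeds pedigree-based expectations.

## Regulatory annotation

Noncoding variants (in practice: rare inherited homozygous variants inside
ROHs) are intersected with brain epigenome tracks: a variant inside a brain
H3K4me3 peak is a predicted brain *promoter* variant, upgraded to
*brain-specific* when no `1_Active_Promoter` chromatin state of any of the
nine non-neuronal cell lines overlaps it; a variant inside a predicted
regulatory element (pRE) is a brain *enhancer* variant, brain-specific when
no `4_Strong_Enhancer`/`5_Strong_Enhancer` state overlaps. Both calls can
co-occur. Overlap semantics: an SNV at VCF position $p$ overlaps a disk
interval $[s, e)$ iff $s < p \le e$; indels use the REF footprint — the
choice for footprints spanning an element boundary is intersection, flagged
per call. Fewer than nine cell-line tracks triggers a warning, not an
error. Promoter-enhancer interaction pairs link a variant's element to
target genes when the far anchor overlaps the gene's promoter; supporting
activating marks (H3K4me1/H3K27ac) are reported alongside.

## Burden analysis

Effects are classified ND (synonymous SNV, non-frameshift indel), MD
(nonsynonymous SNV meeting at least two of SIFT < 0.05, PolyPhen-2 HumVar
> 0.15, PROVEAN < −2.5, MutationAssessor > 2.26; missing scores cannot
support MD), or LoF (splice site, stopgain, stoploss, frameshift indel);
everything else is excluded from burden tables with a logged count. Rates
inside ROHs divide counts by each individual's total ROH length; outside
rates divide by the remaining callable genome (the within-ROH denominator
is the defined one; the per-10^8-bp display of inside *and* outside rates
forces the dual-denominator reading), both per 10^8 bp. Contrasts use
Welch's unpaired t-test by default (`var_equal = TRUE` gives the pooled
form); p-values are reported raw, without multiplicity correction, matching
standard practice for these descriptive contrasts. Constraint comparison
averages gnomAD pLI/pRec/pNull over the genes carrying qualifying variants
inside versus outside ROHs.

## Prioritization

Candidate calls are retained when rare and frameshift / stopgain / stoploss
/ splicing / unknown-effect (kept so splice-site variants with unannotated
protein effect survive) / deleterious nonsynonymous. Subpopulation
deprioritization removes coding variants with MAF $\ge$ 1%, and noncoding
variants with MAF > 0.1% or any homozygote, in any subpopulation relevant
to the family's ancestry (supplied per family). Tiers are a pure function
of a rationale vector of named criteria — deprioritized, known gene
(SFARI/NDD-listed), brain expression, deleteriousness, brain-specific
element, interaction validation, coding status — so every emitted call is
auditably recomputable from its own rationale string. The default rule
table: deprioritized $\to$ excluded; known gene, or (coding $\wedge$
brain-expressed $\wedge$ deleterious), or (noncoding $\wedge$
brain-specific $\wedge$ interaction-validated) $\to$ high; any single
evidence line $\to$ medium; otherwise low. Exact precedence between partial
evidence lines is not prescribed anywhere authoritative, so the table is an
editable object (`default_tier_rules()`) and alternative readings are a
one-line change; conservation scores (CADD/phastCons/phyloP/GERP) are
carried as evidence but do not gate tiers by default because no printed
cutoffs exist for them. Per-sample reports select high-priority calls,
falling back to medium when an affected individual has none.

## Numerical and degenerate-input choices

* Seeds: one integer seed expands deterministically into per-stage
  substreams, so any stage can be re-run in isolation.
* Chromosomes with fewer retained sites than one window yield no ROH calls.
* Zero variants in a burden cell: the sample is excluded from that fraction
  with a note, never silently.
* Degenerate t-test inputs (constant groups) return p = 1 for equal
  constants and p = 0 for separated constants rather than erroring.
* Multi-allelic VCF records are decomposed before any filter; allele depths
  are re-projected per alternate, and carrier counts are conserved.
* Problem sizes: unit tests run on the ~300 Mb test genome at 5–100
  sites/Mb; the recovery experiments use the full ~2,700 Mb profile at 100
  sites/Mb with 100 children per union type — large enough that the
  3-standard-error bands around 6.25%/12.5% are decisive, small enough for
  a desk machine.

## Known limitations

The generator's clean-genotype assumption means recovery rates here are
upper bounds for real data. The X model omits PAR recombination and male X
ROH metrics (metrics are autosomal-only by definition). Gene models are
uniform 100 kb bins, so gene-length confounding of burden comparisons is
not represented. The tier rule table encodes one defensible reading of a
multi-criteria prioritization; it is shipped as data precisely so other
readings can be tested.

## A worked example

```{r example, eval = FALSE}
model <- default_genome("test", site_density = 20)
ped <- build_pedigree("first_cousin", n_children = 1)
co <- sim_cohort(ped, model, seed = 33, plant = list(
  plant_spec("de_novo", "FAM1_c1", known_gene = TRUE),
  plant_spec("hom_in_roh", "FAM1_c1")))

vt <- as_variant_table(co)
dn <- call_de_novo(vt, co$pedigree, "FAM1_c1", model = model)
dn[dn$call, c("site_id", "allele_balance")]

auto <- co$sites$chrom != "chrX"
keep <- roh_site_filter(co$geno[auto, ])
segs <- detect_roh(co$geno[auto, "FAM1_c1"][keep], co$sites[auto, ][keep, ],
                   sample_id = "FAM1_c1")
roh_metrics(segs, autosome_length(model))
```
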