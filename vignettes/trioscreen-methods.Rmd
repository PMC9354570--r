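---
title: "Methods: tiered variant prioritization for trio and singleton WGS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered variant prioritization for trio and singleton WGS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(trioscreen)
library(dplyr)
```

# The problem

Deep whole-genome sequencing of a small rare-disease cohort — here
modelled on an infantile-spasms study design of 16 patients, 6 of them
sequenced with both parents — produces millions of variant calls per
genome, of which at most a handful are clinically reportable. trioscreen
implements the narrowing as an explicit, auditable cascade: every filter
is a pure function from a variant table to its kept subset, and every run
carries a funnel trace (`filter_trace()`), so "how did we get from
millions of calls to seven rows" is always answerable.

# The filtration model

## First-pass cohort filters

1. **Genotyping rate.** A site must be genotyped (GT not missing) in
   *more than* half of all sequenced genomes — patients and parents
   alike. The stringent variant of the same filter demands more than 90%.
   Both comparisons are strict, reading "more than half" and "called in
   \>90%" literally; a site genotyped in exactly half the cohort fails.
2. **Repeat and segmental-duplication exclusion.** A variant is removed
   if its position falls in a masked interval *or* its annotation flags
   it as repeat/segdup-located; either evidence suffices. Interval
   structures are 0-based half-open (BED), VCF positions 1-based, and the
   conversion lives in exactly one function (`vcf_pos_to_bed()`) so there
   is a single point of off-by-one truth.

## Allele-frequency ceilings

The model-specific ceilings are strict: AF \< 10⁻³ under a recessive
model, AF \< 10⁻⁵ under a dominant model, required in *every* consulted
database (gnomAD v2, gnomAD v3, Kaviar by default). A record absent from
a database is treated as frequency zero — absence of evidence is the
best evidence available for a private variant — while remaining
distinguishable in the annotation table (stored `NA` vs numeric 0). The
stringent AF-zero filter extends the database list to five population
resources plus an in-house set. Global (all-population) frequencies are
used; per-database population-maximum columns are honoured behind
`filter_config(use_popmax = TRUE)` but off by default, since no
subpopulation strategy is part of the core design.

## Gene tiers and non-silent selection

Gene tiers nest cumulatively: curated epilepsy genes (E) ⊂
seizure-associated genes (S) ⊂ morbid OMIM genes (O); querying tier S
means E∪S. Non-silent selection keeps protein-altering consequences
(missense, nonsense, stop-loss, coding indels, canonical splice) and
additionally any variant predicted splice-altering — dbscSNV RF or ADA
score strictly above 0.6, or a CADD-Splice flag. Scores are consumed as
annotations; the package never recomputes them.

## Stringent per-sample filters

Singleton screening composes, in order: carried-by-sample, genotyping
rate \> 0.9, biallelic original site (exactly one ALT before
multi-allelic decomposition), depth ≥ 15 with VAF ≥ 0.3 (both
non-strict, so depth 15 with VAF exactly 0.3 passes; the same VAF
formula applies to hemizygous calls), AF zero everywhere, and a
dominant-model (AD/XLD) disease gene. Trio paths reuse prefixes of this
list: filters 1–4 for de novo screening, 1–3 for recessive screening.

# Trio inheritance logic

**De novo**: child heterozygous (or hemizygous-alternate on male chrX),
both parents reference with *zero* alternate-supporting reads and depth
≥ 15. The parental depth/evidence requirement mirrors the proband
thresholds; it is a deliberate symmetric choice (tunable via
`filter_config(min_depth=)`) since shallow parental coverage is the main
source of false de novo calls. Missing parental genotypes yield
"uncalled", never de novo.

**Compound heterozygotes** are demanded in trans: within one gene, at
least one child-het record transmitted exclusively by the father and one
exclusively by the mother; all such unordered pairs are emitted. A
record carried by both parents is phase-ambiguous from genotypes alone
and never anchors a pair — a conservative choice that trades a little
sensitivity for zero cis false pairs, given that no statistical or
read-backed phasing is in scope.

**Homozygous recessive** requires both parents heterozygous (not
hom-alt), consistent with unaffected carrier parents under the AF
bounds. **Hemizygous**: male child hemi-alt on chrX with het mother and
hemi-ref father. Single het hits in autosomal-recessive genes are not
reported as candidates (one allele does not satisfy the model); de novo
calls in females on chrX follow autosomal het logic. Pseudo-autosomal
regions are configurable as an interval file in `read_cohort()` and
default to empty, so by default every male chrX call is read as
single-copy.

# CNV deletion consensus

"Seen by both callers" is read as *reciprocal* overlap ≥ 0.70 — the
minimum of the two mutual fractions, the standard symmetric concordance
criterion (one-way overlap is available via
`consensus_config(reciprocal = FALSE)`). Matching is greedy best-first
on descending overlap with each call used once; ties break by smaller
combined length, then coordinate order, making results deterministic.
For call sets that are internally non-overlapping — how real CNV callers
emit per-sample deletions — a call can exceed the 0.7 gate with at most
one call of the other set, so the greedy matching is provably optimal;
the test suite asserts equality with an exhaustive maximum matching on
such instances. Consensus coordinates are the pair's intersection
(union behind a config switch).

Common calls then pass two gates (no 1-bp overlap with any exclusion
region — the strictest reading of "not located in excluding regions" —
and length \< 50 Mb). Unmatched Manta calls are rescued only if PASS,
\< 1 Mb and precise; unmatched Canvas calls only if QUAL ≥ 10 and not
from an over-called sample. Over-calling is judged once per sample as
count \> 3 × median of the *other* samples' counts — the median keeps the
statistic robust to multiple outliers, and there is no re-computation
after removal. Annotation flags a deletion reportable when it overlaps a
morbid gene with pLI ≥ 0.9 (configurable) or a known-pathogenic CNV
region; a hit on a pLI-0 gene is recorded but not reportable.

# Reporting

Diagnostic yields count patients, not variants: a compound-het pair
diagnoses one patient. Percentages are rounded half-up to one decimal
(2/6 → 33.3, 4/16 → 25.0); base R's round-half-even would print 2/16 as
12.5 either way but disagrees on other halves, so the rule is explicit
in `round_half_up()`. VUS enter the "any candidate" yield only when
promoted via an explicit input table — promotion reflects analyst
judgment (splice predictions, gene pLI, phenotype fit), not an
algorithm, so the pipeline refuses to infer it. Candidate tables are
written deterministically with pair rows adjacent.

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions end to end: 6 trios +
10 singletons (28 genomes), mean depth 60× (Poisson per call, binomial
allele split for hets), per-genotype missingness 2% with 5% of sites
poorly genotyped (rate 0.6) to exercise the genotyping-rate filter, 3%
multi-allelic sites to exercise decomposition and the biallelic filter,
and a background allele-frequency spectrum mixing common (≥ 0.01,
weight 0.45), low (10⁻³–10⁻², 0.25), rare (10⁻⁵–10⁻³, 0.20) and
database-absent (0.10) sites. Database-absent background sites segregate
in the cohort at a 2% carrier allele frequency — private-but-present
variation. Founder genotypes are Hardy–Weinberg draws; children receive
Mendelian transmissions, with proper single-copy handling of male chrX.
Region masks tile roughly 45% of the synthetic genome (three chromosomes
of 120/100/60 Mb), so the first-pass removal is dominated by the region
filter, as in real genomes.

Two deliberate idealizations define the *noiseless* default:

- **Background variants are non-coding/silent only** (intronic,
  intergenic, UTR, synonymous; no splice predictions). This mirrors the
  fact that the overwhelming majority of private variation is
  non-coding, and it makes planted sensitivity and precision
  well-defined: every non-silent, model-consistent finding is a plant.
  Passing tests therefore demonstrate the *mechanism* (each filter and
  inheritance rule does what it claims), not performance on real data,
  where coding background, sequencing artifacts, mosaicism and
  annotation errors all erode precision.
- **Plant depths are designed**, e.g. the de novo plant carries 28/32
  ref/alt reads with clean, well-covered reference parents.

The planted set covers each class once: a de novo stopgain in an E-tier
AD gene, an in-trans compound-het pair in an S-tier AR gene, a
deep-intronic de novo (VUS, promoted), a maternally inherited X-linked
hemizygous splice-region variant (ADA 0.7, VUS, promoted), and two
singleton dominant hits. The scale — 5,000 background sites cohort-wide
rather than millions per genome — keeps a full run in seconds; the
funnel's *shape* (monotone decrease, chaining counts, AF-tier ordering)
is asserted rather than absolute counts, which are data-dependent.

`generate_cnv_callsets()` plants true deletions (dual-caller with
breakpoint jitter, plus clean caller-specific calls) and designed false
calls violating each rescue gate, inflates one sample's Canvas count
(5× rate with a floor at 0.8 × factor × mean so the over-call property
holds by construction, not by luck), and emits the exclusion/morbid-gene
/pathogenic-region/pLI side files. Jitter moves each breakpoint by at
most *f*·len/2 per caller, bounding reciprocal overlap below by
(1−*f*)/(1+*f*); at the maximum supported *f* = 0.15 that is 0.739,
still above the 0.70 gate.

# Numerical and degenerate-input choices

- Multi-allelic sites are decomposed one record per ALT; indels are
  assumed caller-normalized and are not left-aligned here.
- Missing AD with present DP is accepted as `DP,0` for hom-ref calls
  only; carriers without usable depths fail depth/VAF filters
  (conservative).
- VAF is undefined (NA) at zero depth and never passes a VAF threshold.
- Empty inputs flow through: empty BED → empty index (all queries
  false); empty candidate set → header-only table and all-zero yields.
- `"chr1"` and `"1"` are normalized to one namespace in every reader.

# Worked-example fixture

The `inst/extdata` example cohort is a synthetic reconstruction of a
published-style 16-patient candidate table: the seven candidate variants
carry the printed zygosities and allele counts, and all other genotypes
are invented hom-ref calls at ~60× depth. Running `run_pipeline()` on it
recovers all seven candidates and the yields 25.0% (P/LP), 33.3%
(trios), 20.0% (singletons) and 37.5% (with the two promoted VUS) — see
the README for the exact printed output.

```{r example}
d <- system.file("extdata", package = "trioscreen")
res <- run_pipeline(
  vcf = file.path(d, "example.vcf"),
  ped = file.path(d, "example.ped"),
  annotations = file.path(d, "example_annotations.tsv"),
  gene_sets = file.path(d, "example_gene_sets.tsv"),
  promote = tibble(sample_id = c("IS05", "IS06"),
                   variant_id = c("chr12:24000000:C>T",
                                  "chrX:50000000:A>G")))
glance(res)
```

# Known limitations

- No statistical or read-backed phasing: compound-het detection is
  strictly transmission-based, so genes where both parents carry the
  same variant are invisible to it.
- No mosaicism modelling; the strict zero-alt-read parental rule will
  reject true de novo variants in parents with low-level mosaicism.
- ACMG classification, CADD/dbscSNV scores and liftover are consumed as
  annotations, never computed; garbage in, garbage out.
- Duplications, inversions and breakend graphs are out of scope for the
  CNV branch, which handles large deletions only.
- The synthetic generator does not emulate read-level artifacts,
  realistic site-frequency spectra, or linkage between sites.
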