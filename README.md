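# trioscreen

Rare-variant prioritization for small whole-genome cohorts that mix
parent–child trios and singletons, built for early-infancy epilepsy
(infantile spasms / developmental and epileptic encephalopathy) studies
where a handful of patients are sequenced deeply and candidate variants
must be narrowed from millions of calls to a reviewable table.

## What it does

The package implements a tiered prioritization scheme as a set of
pipeable, tibble-in/tibble-out functions:

- **Stepwise SNV/indel filtration** — cohort genotyping rate (> 50%),
  repeat/segmental-duplication exclusion, allele-frequency ceilings that
  depend on the disease model (AF < 10⁻³ for recessive, AF < 10⁻⁵ for
  dominant, evaluated across gnomAD v2/v3 and Kaviar with *absent = 0*),
  cumulative gene tiers (curated epilepsy ⊂ seizure-associated ⊂ morbid
  OMIM), and non-silent selection that admits predicted splice-altering
  variants (dbscSNV RF/ADA > 0.6 or a CADD-Splice flag).
- **Stringent per-sample filters** for singletons: genotyped in > 90% of
  the cohort, biallelic site, depth ≥ 15 with variant allele fraction
  VAF = alt/(ref+alt) ≥ 0.3, AF = 0 in five databases, and a
  dominant-model disease gene. Trio screening reuses subsets of this list
  (filters 1–4 for de novo, 1–3 for recessive).
- **Trio inheritance discovery** — de novo (child het/hemizygous, both
  parents reference with zero alternate reads at depth ≥ 15), homozygous
  recessive, in-trans compound heterozygotes (one allele transmitted
  exclusively by each parent; phase-ambiguous records never anchor a
  pair), and X-linked hemizygous calls.
- **Dual-caller CNV deletion consensus** — Manta- and Canvas-style call
  sets merged by reciprocal overlap ≥ 0.70 with greedy best-first
  one-to-one matching, < 50 Mb and exclusion-region gates, caller-specific
  rescue filters (Manta: PASS, < 1 Mb, precise; Canvas: QUAL ≥ 10 and not
  from an over-called sample, i.e. one whose deletion count exceeds 3× the
  median of the others), and morbid-gene/pLI + pathogenic-region
  annotation.
- **Reporting** — per-patient candidate tables, filtration-funnel traces,
  per-tier variant count matrices, and diagnostic-yield summaries with
  per-patient counting and half-up rounding.
- **Synthetic cohort generator** — a seeded, fully self-contained bundle
  (multi-sample VCF, PED, annotation TSV, gene sets, region BEDs,
  dual-caller CNV call sets, truth tables) that emulates a 28-genome
  cohort of 6 trios + 10 singletons with planted causal variants of every
  inheritance class, so the whole pipeline is testable without sequencing
  data.

## Worked example

The package ships a small example cohort
(`inst/extdata/example.{vcf,ped}` plus annotation and gene-set tables):
16 patients, of whom 6 were sequenced as trios, carrying one candidate of
each inheritance class the screen detects.

```r
library(trioscreen)
d <- system.file("extdata", package = "trioscreen")
res <- run_pipeline(
  vcf = file.path(d, "example.vcf"),
  ped = file.path(d, "example.ped"),
  annotations = file.path(d, "example_annotations.tsv"),
  gene_sets = file.path(d, "example_gene_sets.tsv"),
  promote = dplyr::tibble(
    sample_id = c("IS05", "IS06"),
    variant_id = c("chr12:24000000:C>T", "chrX:50000000:A>G")))
res
#> <pipeline_result> 7 candidate variant(s) in 6 patient(s)
#> <cohort_summary> 16 patients (6 trios, 10 singletons)
#>   P/LP yield 25.0% (trios 33.3%, singletons 20.0%); any-candidate yield 37.5%
tidy(res)[, c("sample_id", "gene", "inheritance_pattern", "model",
              "classification")]
#> # A tibble: 7 x 5
#>   sample_id gene    inheritance_pattern model classification
#> 1 IS01      HDAC4   de_novo_het         AD    P
#> 2 IS02      GRM7    compound_het        AR    LP
#> 3 IS02      GRM7    compound_het        AR    LP
#> 4 IS05      SOX5    de_novo_het         AD    VUS
#> 5 IS06      SHROOM4 hemizygous          XLR   VUS
#> 6 IS11      CACNA1E het_dominant        AD    LP
#> 7 IS15      KMT2E   het_dominant        AD    P
```

Reading the output: four patients carry pathogenic or likely-pathogenic
(P/LP) candidates — a de novo nonsense variant (`HDAC4`), an in-trans
compound-heterozygous pair (`GRM7`), and two singleton dominant hits
(`CACNA1E`, `KMT2E`) — giving a 25.0% diagnostic yield (4/16), 33.3%
among trios (2/6) and 20.0% among singletons (2/10). Two further
analyst-promoted VUS (a deep-intronic de novo in `SOX5` and an X-linked
hemizygous splice-region variant in `SHROOM4`) raise the any-candidate
yield to 37.5% (6/16). `glance(res)` returns the one-row summary,
`autoplot(res)` draws the filtration funnel, and
`plot_tier_counts(res$tier_counts)` the per-tier count bars.

A fully synthetic cohort with the same layout comes from the generator:

```r
spec <- cohort_spec(seed = 1)              # 6 trios + 10 singletons, 28 genomes
bundle <- generate_cohort(spec)            # VCF/PED/annotations/BEDs + truth
cnv <- generate_cnv_callsets(spec)         # Manta/Canvas-style deletions
```

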