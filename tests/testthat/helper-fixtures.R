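# Shared fixtures: the default synthetic bundle is generated once per test
# run and reused; small hand-built tables for filter unit tests; brute-force
# oracles for the interval and matching properties.

.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_cohort(
      cohort_spec(seed = 101L), file.path(tempdir(), "ts_default_cohort"))
  }
  .fixture_cache$bundle
}

default_cnv_bundle <- function() {
  if (is.null(.fixture_cache$cnv)) {
    .fixture_cache$cnv <- generate_cnv_callsets(
      cohort_spec(seed = 101L), file.path(tempdir(), "ts_default_cnv"))
  }
  .fixture_cache$cnv
}

default_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    b <- default_bundle()
    cv <- default_cnv_bundle()
    promote <- b$truth[b$truth$promoted, c("sample_id", "variant_id")]
    .fixture_cache$pipeline <- run_pipeline(
      vcf = b$paths$vcf, ped = b$paths$ped,
      annotations = b$paths$annotations,
      gene_sets = c(b$paths$genes_e, b$paths$genes_s, b$paths$genes_o),
      region_beds = c(b$paths$repeats, b$paths$segdups),
      cnv_manta = cv$paths$manta, cnv_canvas = cv$paths$canvas,
      cnv_exclusion = cv$paths$exclusion,
      cnv_morbid_genes = cv$paths$morbid_genes,
      cnv_pathogenic = cv$paths$pathogenic, cnv_pli = cv$paths$pli,
      promote = promote)
  }
  .fixture_cache$pipeline
}

example_paths <- function() {
  d <- system.file("extdata", package = "trioscreen")
  list(vcf = file.path(d, "example.vcf"),
       ped = file.path(d, "example.ped"),
       annotations = file.path(d, "example_annotations.tsv"),
       gene_sets = file.path(d, "example_gene_sets.tsv"))
}

example_promotions <- function() {
  tibble::tibble(sample_id = c("IS05", "IS06"),
                 variant_id = c("chr12:24000000:C>T", "chrX:50000000:A>G"))
}

# Annotated variant table skeleton for filter unit tests; override any
# column via named arguments.
toy_variants <- function(n, ...) {
  v <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    site_id = sprintf("s%03d", seq_len(n)),
    chrom = "chr1",
    pos = seq_len(n) * 100L,
    ref = "A", alt = "T",
    n_alt_site = 1L,
    gene = NA_character_,
    consequence = "nonsynonymous_snv",
    af_gnomad_v2 = NA_real_, af_gnomad_v3 = NA_real_, af_kaviar = NA_real_,
    af_krgdb = NA_real_, af_togovar = NA_real_, af_inhouse = NA_real_,
    cadd = NA_real_, rf_score = NA_real_, ada_score = NA_real_,
    cadd_splice_flag = FALSE, acmg_class = "unclassified",
    clinvar_reported = FALSE, in_repeat_or_segdup = FALSE
  )
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# Uniform genotype rows for toy variant tables.
toy_genotypes <- function(variants, samples, gt = "het",
                          ref_depth = 30L, alt_depth = 30L) {
  tidyr::expand_grid(variant_id = variants$variant_id, sample_id = samples) |>
    dplyr::mutate(gt = gt, ref_depth = ref_depth, alt_depth = alt_depth)
}

# Brute-force point-in-intervals scan (the oracle for the interval index).
bf_point_in <- function(chrom, pos, intervals) {
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start < pos[i] & pos[i] <= intervals$end)
  }, logical(1))
}

# Brute-force maximum one-to-one matching count among caller pairs whose
# reciprocal overlap meets the gate (exhaustive recursion; fine for <= 10
# calls per caller).
bf_max_matching <- function(manta, canvas, min_overlap = 0.7) {
  ok <- outer(seq_len(nrow(manta)), seq_len(nrow(canvas)),
              Vectorize(function(i, j) {
                reciprocal_overlap(manta$chrom[i], manta$start[i], manta$end[i],
                                   canvas$chrom[j], canvas$start[j],
                                   canvas$end[j]) >= min_overlap
              }))
  recurse <- function(i, used) {
    if (i > nrow(manta)) return(0L)
    best <- recurse(i + 1L, used)  # skip manta call i
    for (j in seq_len(nrow(canvas))) {
      if (ok[i, j] && !(j %in% used)) {
        best <- max(best, 1L + recurse(i + 1L, c(used, j)))
      }
    }
    best
  }
  recurse(1L, integer(0))
}

# Random within-caller-disjoint call set (how a real caller emits calls).
random_disjoint_calls <- function(n, caller, sample_id = "S1") {
  len <- sample(5000:15000, n, replace = TRUE)
  gaps <- sample(20000:60000, n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(dplyr::lag(len, default = 0L))
  tibble::tibble(caller = caller, sample_id = sample_id, chrom = "chr1",
                 start = as.integer(starts), end = as.integer(starts + len),
                 filter = "PASS", qual = 30, imprecise = FALSE,
                 call_id = sprintf("%s_%03d", caller, seq_len(n)))
}

# Jittered copy of calls, relabelled to the other caller; jitter fraction f
# keeps reciprocal overlap >= (1 - f) / (1 + f).
jittered_copy <- function(calls, new_caller, f = 0.1) {
  len <- calls$end - calls$start
  calls$caller <- new_caller
  calls$start <- as.integer(calls$start +
                              round(runif(nrow(calls), -f / 2, f / 2) * len))
  calls$end <- as.integer(calls$end +
                            round(runif(nrow(calls), -f / 2, f / 2) * len))
  calls$call_id <- sprintf("%s_%03d", new_caller, seq_len(nrow(calls)))
  calls
}
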