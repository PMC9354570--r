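# Stepwise SNV/indel filtration cascade. Every filter takes the annotated
# variant table first, returns the kept subset as a tibble, and appends a
# (step, n_in, n_out) row to the table's filter trace, so the funnel can be
# reconstructed from any chain of piped filters.
#
# Inequality conventions (deliberate, see the methods vignette):
#   * allele-frequency thresholds are strict (<)
#   * depth and VAF thresholds are non-strict (>=)
#   * genotyped-fraction thresholds are strict (>) for both the 0.5 and 0.9
#     settings
#   * dbscSNV splice scores are strict (> 0.6)

#' Filtration thresholds for the SNV prioritization cascade
#'
#' @param min_genotyped_fraction_step1 Cohort genotyping-rate threshold for
#'   the first-pass filter (strict `>`; default 0.5).
#' @param min_genotyped_fraction_stringent Genotyping-rate threshold in the
#'   stringent filter set (strict `>`; default 0.9).
#' @param af_recessive_max Allele-frequency ceiling under a recessive model
#'   (strict `<`; default 1e-3).
#' @param af_dominant_max Allele-frequency ceiling under a dominant model
#'   (strict `<`; default 1e-5).
#' @param min_depth Minimum coverage depth, in reads (`>=`; default 15).
#'   Also required of both parents when calling a variant de novo.
#' @param min_vaf Minimum variant allele fraction (`>=`; default 0.3).
#' @param splice_score_min dbscSNV RF/ADA score threshold (strict `>`;
#'   default 0.6).
#' @param af_step_databases Databases consulted by the model-specific AF
#'   filter (default gnomAD v2/v3 and Kaviar).
#' @param af_zero_databases Databases in which a variant must be unobserved
#'   to pass the stringent AF-zero filter (default all five population
#'   databases plus the in-house set).
#' @param use_popmax Use per-database population-maximum AF columns
#'   (`af_<db>_popmax`) when present instead of the global AF.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_genotyped_fraction_step1 = 0.5,
                          min_genotyped_fraction_stringent = 0.9,
                          af_recessive_max = 1e-3,
                          af_dominant_max = 1e-5,
                          min_depth = 15,
                          min_vaf = 0.3,
                          splice_score_min = 0.6,
                          af_step_databases = c("gnomad_v2", "gnomad_v3",
                                                "kaviar"),
                          af_zero_databases = c("gnomad_v2", "gnomad_v3",
                                                "kaviar", "krgdb", "togovar",
                                                "inhouse"),
                          use_popmax = FALSE) {
  stopifnot(min_genotyped_fraction_step1 >= 0,
            min_genotyped_fraction_step1 <= 1,
            min_genotyped_fraction_stringent >= 0,
            min_genotyped_fraction_stringent <= 1,
            min_vaf >= 0, min_vaf <= 1,
            af_dominant_max <= af_recessive_max)
  structure(as.list(environment()), class = "filter_config")
}

# ---- filter trace ----------------------------------------------------------

#' Extract the filtration funnel trace of a filtered variant table
#'
#' @param x A variant tibble that has passed through one or more filters.
#' @return A tibble of class `filter_trace` with columns `step`, `n_in`,
#'   `n_out`, in application order.
#' @export
filter_trace <- function(x) {
  tr <- attr(x, "filter_trace")
  if (is.null(tr)) {
    tr <- tibble(step = character(), n_in = integer(), n_out = integer())
  }
  structure(tr, class = c("filter_trace", class(tibble())))
}

add_trace <- function(out, input, step) {
  tr <- filter_trace(input)
  tr <- dplyr::bind_rows(tibble::as_tibble(tr),
                         tibble(step = step, n_in = nrow(input),
                                n_out = nrow(out)))
  attr(out, "filter_trace") <- tr
  out
}

#' Plot a filtration funnel
#'
#' @param object A [filter_trace()] table.
#' @param ... Unused.
#' @return A ggplot bar chart of surviving variant counts per step.
#' @method autoplot filter_trace
#' @export
autoplot.filter_trace <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    mutate(step = factor(.data$step, levels = unique(.data$step)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "variants surviving") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# ---- individual filters ----------------------------------------------------

#' Keep variants genotyped in more than a fraction of the cohort
#'
#' "Genotyped" means the GT call is not missing. The comparison is strict:
#' a site genotyped in exactly half the samples fails the 0.5 setting.
#'
#' @param variants Variant table.
#' @param genotypes Long genotype table ([read_cohort()]).
#' @param samples Sample ids forming the denominator (normally every
#'   sequenced genome, parents included).
#' @param min_fraction Threshold fraction.
#' @return The kept subset of `variants`, with an updated filter trace.
#' @export
filter_genotyped_fraction <- function(variants, genotypes, samples,
                                      min_fraction = 0.5) {
  frac <- genotypes |>
    filter(.data$sample_id %in% samples) |>
    group_by(.data$variant_id) |>
    summarise(frac = sum(.data$gt != "missing") / length(samples),
              .groups = "drop")
  keep_ids <- frac$variant_id[frac$frac > min_fraction]
  out <- variants |> filter(.data$variant_id %in% keep_ids)
  add_trace(out, variants,
            sprintf("genotyped_fraction>%s", format(min_fraction)))
}

#' Remove variants in repeat or segmental-duplication regions
#'
#' A record is dropped when its position falls inside any masked interval or
#' when its `in_repeat_or_segdup` annotation flag is set; either evidence
#' suffices.
#'
#' @param variants Annotated variant table.
#' @param region_index Interval table from [read_regions()].
#' @return The kept subset, with an updated filter trace.
#' @export
filter_repeat_segdup <- function(variants, region_index) {
  in_region <- points_in_regions(variants$chrom, variants$pos, region_index)
  flagged <- variants$in_repeat_or_segdup %||% rep(FALSE, nrow(variants))
  flagged <- dplyr::coalesce(flagged, FALSE)
  out <- variants[!(in_region | flagged), , drop = FALSE]
  add_trace(out, variants, "repeat_segdup")
}

# AF matrix for the listed databases; absent (NA) is frequency zero.
af_matrix <- function(variants, databases, use_popmax = FALSE) {
  cols <- map_chr(databases, function(db) {
    pm <- paste0("af_", db, "_popmax")
    if (use_popmax && pm %in% colnames(variants)) pm else paste0("af_", db)
  })
  miss <- setdiff(cols, colnames(variants))
  if (length(miss) > 0) {
    abort(sprintf("annotation column(s) not found: %s",
                  paste(miss, collapse = ", ")))
  }
  m <- as.matrix(variants[, cols, drop = FALSE])
  m[is.na(m)] <- 0
  m
}

#' Filter by allele frequency under a dominant or recessive model
#'
#' Keeps variants whose frequency is strictly below the model's ceiling in
#' every consulted database; absence from a database counts as zero.
#'
#' @param variants Annotated variant table.
#' @param model `"dominant"` (AF < 1e-5) or `"recessive"` (AF < 1e-3).
#' @param config A [filter_config()].
#' @return The kept subset, with an updated filter trace.
#' @export
filter_allele_frequency <- function(variants, model,
                                    config = filter_config()) {
  if (!model %in% c("dominant", "recessive")) {
    abort(sprintf("unknown inheritance model '%s'", model))
  }
  thr <- if (model == "dominant") config$af_dominant_max else config$af_recessive_max
  m <- af_matrix(variants, config$af_step_databases, config$use_popmax)
  keep <- if (nrow(variants) == 0) logical(0) else
    apply(m < thr, 1, all)
  out <- variants[keep, , drop = FALSE]
  add_trace(out, variants, sprintf("af_%s<%g", model, thr))
}

#' Keep variants unobserved in all listed frequency databases
#'
#' A variant passes when it is absent from, or has a stored frequency of
#' exactly zero in, every listed database.
#'
#' @param variants Annotated variant table.
#' @param databases Database ids (default the registry of
#'   [filter_config()]'s `af_zero_databases`).
#' @return The kept subset, with an updated filter trace.
#' @export
filter_af_zero <- function(variants,
                           databases = filter_config()$af_zero_databases) {
  m <- af_matrix(variants, databases)
  keep <- if (nrow(variants) == 0) logical(0) else apply(m == 0, 1, all)
  out <- variants[keep, , drop = FALSE]
  add_trace(out, variants, "af_zero")
}

#' Restrict variants to a cumulative gene tier
#'
#' Tiers nest: `"E"` keeps only curated-epilepsy genes, `"S"` keeps
#' curated-epilepsy plus seizure-associated genes, `"O"` additionally keeps
#' morbid OMIM genes, `"any"` keeps everything including gene-less records.
#'
#' @param variants Annotated variant table.
#' @param catalog A [read_gene_sets()] catalog.
#' @param tier `"E"`, `"S"`, `"O"` or `"any"`.
#' @return The kept subset, with an updated filter trace.
#' @export
filter_gene_tier <- function(variants, catalog, tier) {
  if (identical(tier, "any")) {
    out <- variants
  } else {
    keep <- catalog_gene_in_tier(catalog, variants$gene, tier)
    out <- variants[keep, , drop = FALSE]
  }
  add_trace(out, variants, sprintf("gene_tier_%s", tier))
}

#' Select non-silent variants, including predicted splice-altering ones
#'
#' Keeps protein-altering consequences (missense, nonsense, stoploss,
#' coding indels, canonical splice) plus any record predicted
#' splice-altering by dbscSNV (RF or ADA score above the threshold) or
#' flagged by CADD-Splice.
#'
#' @param variants Annotated variant table.
#' @param config A [filter_config()].
#' @return The kept subset, with an updated filter trace.
#' @export
select_nonsilent <- function(variants, config = filter_config()) {
  thr <- config$splice_score_min
  keep <- variants$consequence %in% NONSILENT_CONSEQUENCES |
    dplyr::coalesce(variants$rf_score > thr, FALSE) |
    dplyr::coalesce(variants$ada_score > thr, FALSE) |
    dplyr::coalesce(variants$cadd_splice_flag, FALSE)
  out <- variants[keep, , drop = FALSE]
  add_trace(out, variants, "nonsilent")
}

# ---- stringent filter set --------------------------------------------------

STRINGENT_MODES <- c("singleton_dominant", "trio_denovo", "trio_recessive")

#' Apply the stringent per-sample filter set
#'
#' The full set, used for singleton dominant-model screening, is:
#' (1) site genotyped in more than 90% of the cohort; (2) the original VCF
#' site was biallelic (exactly one ALT allele); (3) the named sample's call
#' has depth >= 15 and VAF >= 0.3; (4) allele frequency zero in every
#' registered database; (5) the gene carries a dominant disease model
#' (AD or XLD). Trio screening reuses subsets: `trio_denovo` applies
#' filters 1-4 and `trio_recessive` filters 1-3.
#'
#' Records not carried by the sample (no alternate allele in its genotype)
#' are dropped first, since the cascade prioritizes the patient's own
#' variants.
#'
#' @param variants Annotated variant table.
#' @param genotypes Long genotype table.
#' @param sample Sample id whose genotype feeds filter (3).
#' @param mode One of `"singleton_dominant"`, `"trio_denovo"`,
#'   `"trio_recessive"`.
#' @param catalog Gene catalog (needed for filter 5).
#' @param config A [filter_config()].
#' @param cohort_samples Denominator samples for filter (1); defaults to all
#'   samples in `genotypes`.
#' @return The kept subset of `variants`, with the full stringent trace.
#' @export
apply_stringent_filters <- function(variants, genotypes, sample, mode,
                                    catalog = NULL,
                                    config = filter_config(),
                                    cohort_samples = NULL) {
  if (!mode %in% STRINGENT_MODES) {
    abort(sprintf("unknown stringent mode '%s'", mode))
  }
  cohort_samples <- cohort_samples %||% unique(genotypes$sample_id)
  n_filters <- switch(mode, singleton_dominant = 5L, trio_denovo = 4L,
                      trio_recessive = 3L)

  own <- genotypes |>
    filter(.data$sample_id == sample, .data$gt %in% GT_CARRIER)
  out <- variants |> filter(.data$variant_id %in% own$variant_id)
  out <- add_trace(out, variants, sprintf("carried_by_%s", sample))

  out <- filter_genotyped_fraction(out, genotypes, cohort_samples,
                                   config$min_genotyped_fraction_stringent)

  kept <- out |> filter(.data$n_alt_site == 1L)
  out <- add_trace(kept, out, "biallelic_site")

  if (n_filters >= 3) {
    own <- own |>
      mutate(depth = .data$ref_depth + .data$alt_depth,
             vaf = gt_vaf(.data$ref_depth, .data$alt_depth)) |>
      filter(!is.na(.data$depth), .data$depth >= config$min_depth,
             !is.na(.data$vaf), .data$vaf >= config$min_vaf)
    kept <- out |> filter(.data$variant_id %in% own$variant_id)
    out <- add_trace(kept, out, "depth_vaf")
  }
  if (n_filters >= 4) {
    out <- filter_af_zero(out, config$af_zero_databases)
  }
  if (n_filters >= 5) {
    if (is.null(catalog)) abort("a gene catalog is required for filter (5)")
    keep <- catalog_gene_has_model(catalog, out$gene, c("AD", "XLD"))
    kept <- out[keep, , drop = FALSE]
    out <- add_trace(kept, out, "dominant_disease_gene")
  }
  out
}
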