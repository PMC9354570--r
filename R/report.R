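# Candidate tables, per-tier count matrices, and cohort diagnostic-yield
# summaries.

# Percentages are reported rounded half-up to one decimal (2/6 -> 33.3,
# 4/16 -> 25.0); base round() rounds half to even, which is not what
# clinical yield tables print.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize diagnostic yield of a candidate table
#'
#' Counts each patient once regardless of how many candidates they carry
#' (a compound-het pair diagnoses one patient). Pathogenic/likely-pathogenic
#' (P/LP) candidates define the diagnostic yield; variants of unknown
#' significance contribute to the "any candidate" yield only when promoted
#' by the analyst (the `promoted` column), since VUS promotion is a judgment
#' call, not an algorithm.
#'
#' @param candidates Candidate tibble ([screen_trio()] /
#'   [screen_singletons()]), optionally with a logical `promoted` column.
#' @param pedigree Pedigree table; affected samples define the denominator.
#' @return A one-row tibble of class `cohort_summary`: patient counts and
#'   the four yields (`yield_plp`, `yield_trio`, `yield_singleton`,
#'   `yield_any`), as percentages rounded half-up to one decimal.
#' @export
summarize_cohort <- function(candidates, pedigree) {
  patients <- pedigree |> filter(.data$affected)
  trios <- patients$sample_id[patients$role == "trio_proband"]
  singles <- patients$sample_id[patients$role == "singleton"]
  if (!"promoted" %in% colnames(candidates)) candidates$promoted <- FALSE
  plp <- candidates |>
    filter(.data$classification %in% c("P", "LP")) |>
    distinct(.data$sample_id)
  any_cand <- candidates |>
    filter(.data$classification %in% c("P", "LP") |
             dplyr::coalesce(.data$promoted, FALSE)) |>
    distinct(.data$sample_id)
  pct <- function(k, n) if (n == 0) 0 else round_half_up(100 * k / n, 1)
  out <- tibble(
    n_patients = nrow(patients),
    n_trios = length(trios),
    n_singletons = length(singles),
    n_diagnosed_plp = nrow(plp),
    n_with_any_candidate = nrow(any_cand),
    yield_plp = pct(nrow(plp), nrow(patients)),
    yield_trio = pct(sum(plp$sample_id %in% trios), length(trios)),
    yield_singleton = pct(sum(plp$sample_id %in% singles), length(singles)),
    yield_any = pct(nrow(any_cand), nrow(patients))
  )
  structure(out, class = c("cohort_summary", class(out)))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d patients (%d trios, %d singletons)\n  P/LP yield %.1f%% (trios %.1f%%, singletons %.1f%%); any-candidate yield %.1f%%\n",
    x$n_patients, x$n_trios, x$n_singletons, x$yield_plp, x$yield_trio,
    x$yield_singleton, x$yield_any))
  invisible(x)
}

# Region class of a consequence, for the per-tier count matrices.
region_class <- function(consequence) {
  dplyr::case_when(
    consequence %in% c("nonsynonymous_snv", "stopgain", "stoploss",
                       "frameshift_indel", "inframe_indel", "synonymous") ~ "CDS",
    consequence == "utr" ~ "UTR",
    consequence %in% c("intronic", "canonical_splice") ~ "intron",
    .default = NA_character_
  )
}

#' Per-sample, per-tier variant count matrix
#'
#' Counts database-absent (AF = 0) variants carried by each sample within
#' each cumulative gene tier (E; E+S; E+S+O), split by region class (CDS,
#' UTR, intron), and separately for the de novo subset when supplied. The
#' cumulative-tier counts are therefore monotone: S >= E, O >= S.
#'
#' @param variants Annotated variant table, already restricted to the set to
#'   count (typically AF-zero variants).
#' @param genotypes Long genotype table (defines which sample carries which
#'   variant).
#' @param catalog Gene catalog.
#' @param samples Sample ids to count (default: all in `genotypes`).
#' @param de_novo_ids Optional variant/sample pairs (tibble `variant_id`,
#'   `sample_id`) marking de novo calls for the de novo layer.
#' @return A tidy tibble: `sample_id`, `tier`, `region`, `origin`
#'   (`"all"`/`"de_novo"`), `n`.
#' @export
tier_count_matrix <- function(variants, genotypes, catalog, samples = NULL,
                              de_novo_ids = NULL) {
  samples <- samples %||% unique(genotypes$sample_id)
  carried <- genotypes |>
    filter(.data$sample_id %in% samples, .data$gt %in% GT_CARRIER) |>
    select("variant_id", "sample_id") |>
    inner_join(variants, by = "variant_id") |>
    mutate(region = region_class(.data$consequence)) |>
    filter(!is.na(.data$region), !is.na(.data$gene))
  grid <- tidyr::expand_grid(sample_id = samples, tier = TIERS,
                             region = c("CDS", "UTR", "intron"),
                             origin = "all")
  count_layer <- function(d, origin) {
    purrr::map(TIERS, function(tr) {
      d[catalog_gene_in_tier(catalog, d$gene, tr), , drop = FALSE] |>
        count(.data$sample_id, .data$region) |>
        mutate(tier = tr, origin = origin)
    }) |> list_rbind()
  }
  layers <- count_layer(carried, "all")
  if (!is.null(de_novo_ids)) {
    dn <- carried |>
      inner_join(de_novo_ids, by = c("variant_id", "sample_id"))
    grid <- dplyr::bind_rows(grid, grid |> mutate(origin = "de_novo"))
    layers <- dplyr::bind_rows(layers, count_layer(dn, "de_novo"))
  }
  grid |>
    left_join(layers, by = c("sample_id", "tier", "region", "origin")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    arrange(.data$sample_id, match(.data$tier, TIERS), .data$region,
            .data$origin)
}

#' Bar plot of mean per-tier variant counts
#'
#' Figure-style summary of a [tier_count_matrix()]: mean count per
#' cumulative gene tier, stacked by region class, faceted by variant origin.
#'
#' @param counts A [tier_count_matrix()] tibble.
#' @return A ggplot object.
#' @export
plot_tier_counts <- function(counts) {
  d <- counts |>
    group_by(.data$tier, .data$region, .data$origin) |>
    summarise(mean_n = mean(.data$n), .groups = "drop") |>
    mutate(tier = factor(.data$tier, levels = TIERS,
                         labels = c("curated epilepsy", "seizure-associated",
                                    "morbid OMIM")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tier, y = .data$mean_n,
                                  fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~origin, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean variants per sample",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' Write a deterministic candidate table to TSV
#'
#' One row per candidate variant; compound-het pairs appear on adjacent rows
#' sharing a `pair_id`. Byte-identical across re-runs on the same input.
#'
#' @param candidates Candidate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- candidates |>
    arrange(.data$sample_id,
            dplyr::coalesce(.data$pair_id, paste0("zz", .data$variant_id)),
            .data$chrom, .data$pos, .data$variant_id)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
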