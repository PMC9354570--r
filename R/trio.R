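# Inheritance-pattern discovery for trio probands: de novo, homozygous
# recessive, in-trans compound heterozygous, and X-linked hemizygous calls,
# driven by child/father/mother genotype triples.

# Wide per-variant trio genotype table for one proband: one row per variant
# with child/father/mother gt and depths.
trio_genotype_table <- function(genotypes, child, father, mother) {
  roles <- c(child = child, father = father, mother = mother)
  genotypes |>
    filter(.data$sample_id %in% roles) |>
    mutate(role = names(roles)[match(.data$sample_id, roles)]) |>
    select("variant_id", "role", "gt", "ref_depth", "alt_depth") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("gt", "ref_depth", "alt_depth")) |>
    mutate(dplyr::across(dplyr::starts_with("gt_"),
                         ~dplyr::coalesce(.x, "missing")))
}

#' Call candidate de novo variants from trio genotypes
#'
#' A variant is de novo when the child is heterozygous (or hemizygous-alt on
#' male chrX), both parents are reference (hom-ref, or hemi-ref for the
#' father on chrX), neither parent shows a single alternate-supporting read,
#' and each parent's total depth meets `min_depth`. Missing parental
#' genotypes make the variant uncallable, never de novo.
#'
#' @param trio Wide trio genotype table with columns `gt_child`, `gt_father`,
#'   `gt_mother` and the matching `ref_depth_*`/`alt_depth_*` columns.
#' @param min_depth Minimum parental depth (default 15).
#' @return Logical vector along the rows of `trio`.
#' @export
call_de_novo <- function(trio, min_depth = 15) {
  parent_clear <- function(gt, rd, ad, ref_states) {
    gt %in% ref_states &
      dplyr::coalesce(ad, 1L) == 0L &
      dplyr::coalesce(rd + ad, 0L) >= min_depth
  }
  child_carries <- trio$gt_child %in% c("het", "hemi_alt")
  father_ok <- parent_clear(trio$gt_father, trio$ref_depth_father,
                            trio$alt_depth_father, c("hom_ref", "hemi_ref"))
  mother_ok <- parent_clear(trio$gt_mother, trio$ref_depth_mother,
                            trio$alt_depth_mother, "hom_ref")
  child_carries & father_ok & mother_ok
}

# Single-record inheritance state used by the partition invariant: exactly
# one of de_novo_het / hom_recessive / hemizygous / inherited / uncalled.
classify_trio_record <- function(trio, min_depth = 15) {
  de_novo <- call_de_novo(trio, min_depth)
  dplyr::case_when(
    trio$gt_child == "missing" | trio$gt_father == "missing" |
      trio$gt_mother == "missing" ~ "uncalled",
    de_novo & trio$gt_child == "het" ~ "de_novo_het",
    de_novo & trio$gt_child == "hemi_alt" ~ "hemizygous",
    trio$gt_child == "hom_alt" & trio$gt_father == "het" &
      trio$gt_mother == "het" ~ "hom_recessive",
    trio$gt_child == "hemi_alt" & trio$gt_mother == "het" &
      trio$gt_father == "hemi_ref" ~ "hemizygous",
    trio$gt_child %in% GT_CARRIER ~ "inherited",
    .default = "not_carried"
  )
}

# Exclusive parental transmission of a child-het record: "father" when the
# father carries the allele and the mother is reference, vice versa for
# "mother"; "ambiguous" when both parents carry it (phase unknowable from
# genotypes alone) and "none" otherwise.
transmission_origin <- function(trio) {
  fa <- trio$gt_father %in% GT_CARRIER
  mo <- trio$gt_mother %in% GT_CARRIER
  dplyr::case_when(
    trio$gt_child != "het" ~ "none",
    fa & !mo ~ "father",
    mo & !fa ~ "mother",
    fa & mo ~ "ambiguous",
    .default = "none"
  )
}

#' Call recessive-model variants (homozygous, compound het, hemizygous)
#'
#' Operates on the records of one gene in one trio. Emits:
#' \itemize{
#'   \item `hom_recessive` -- child hom-alt with both parents het;
#'   \item `compound_het` -- every unordered in-trans pair of child-het
#'     records where one is transmitted exclusively by the father and the
#'     other exclusively by the mother. Records carried by both parents are
#'     phase-ambiguous and never anchor a pair;
#'   \item `hemizygous` -- male-child chrX hemi-alt with a het mother and a
#'     hemi-ref father.
#' }
#'
#' @param trio Wide trio genotype table for the gene's records
#'   (`variant_id` column required).
#' @return A tibble with columns `variant_id`, `pattern`,
#'   `parent_of_origin`, `partner_id` (non-`NA` for compound-het pairs),
#'   `pair_id`.
#' @export
call_recessive <- function(trio) {
  state <- classify_trio_record(trio)
  out <- list()
  hom <- trio$variant_id[state == "hom_recessive"]
  if (length(hom) > 0) {
    out$hom <- tibble(variant_id = hom, pattern = "hom_recessive",
                      parent_of_origin = "both", partner_id = NA_character_,
                      pair_id = NA_character_)
  }
  hemi <- trio$variant_id[state == "hemizygous" &
                            trio$gt_mother == "het" &
                            trio$gt_father == "hemi_ref"]
  if (length(hemi) > 0) {
    out$hemi <- tibble(variant_id = hemi, pattern = "hemizygous",
                       parent_of_origin = "mother",
                       partner_id = NA_character_, pair_id = NA_character_)
  }
  origin <- transmission_origin(trio)
  pat <- trio$variant_id[origin == "father"]
  mat <- trio$variant_id[origin == "mother"]
  if (length(pat) > 0 && length(mat) > 0) {
    pairs <- tidyr::expand_grid(a = pat, b = mat)
    pairs$pair_id <- sprintf("pair_%02d", seq_len(nrow(pairs)))
    out$comp <- dplyr::bind_rows(
      tibble(variant_id = pairs$a, pattern = "compound_het",
             parent_of_origin = "father", partner_id = pairs$b,
             pair_id = pairs$pair_id),
      tibble(variant_id = pairs$b, pattern = "compound_het",
             parent_of_origin = "mother", partner_id = pairs$a,
             pair_id = pairs$pair_id)
    )
  }
  if (length(out) == 0) {
    return(tibble(variant_id = character(), pattern = character(),
                  parent_of_origin = character(), partner_id = character(),
                  pair_id = character()))
  }
  dplyr::bind_rows(out) |> arrange(.data$variant_id)
}

#' Screen all trios of a cohort for candidate variants
#'
#' Runs, for each trio proband, the dominant path (stringent filters 1-4,
#' then de novo calling on any gene in the queried tier) and the recessive
#' path (non-silent selection plus stringent filters 1-3, then
#' homozygous / in-trans compound-het / hemizygous calling in genes whose
#' inheritance models allow a recessive interpretation).
#'
#' @param variants Annotated variant table (post step-1/2 cascade or raw).
#' @param genotypes Long genotype table.
#' @param pedigree Pedigree table ([read_pedigree()]).
#' @param catalog Gene catalog ([read_gene_sets()]).
#' @param config A [filter_config()].
#' @param tier Cumulative gene tier for candidate reporting (default `"S"`,
#'   curated-epilepsy plus seizure-associated genes).
#' @return A candidate tibble: `sample_id`, `variant_id`, `gene`, `tier`,
#'   `inheritance_pattern`, `model`, `parent_of_origin`, `classification`,
#'   `ref_depth`, `alt_depth`, `partner_id`, `pair_id`, ordered by
#'   (sample, chrom, pos).
#' @export
screen_trio <- function(variants, genotypes, pedigree, catalog,
                        config = filter_config(), tier = "S") {
  probands <- pedigree |> filter(.data$role == "trio_proband")
  all_samples <- pedigree$sample_id
  out <- purrr::pmap(
    list(probands$sample_id, probands$father_id, probands$mother_id),
    function(child, father, mother) {
      screen_one_trio(variants, genotypes, child, father, mother,
                      catalog, config, tier, all_samples)
    }) |>
    list_rbind()
  if (nrow(out) == 0) return(empty_candidates())
  finalize_candidates(out, genotypes, catalog) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)
}

screen_one_trio <- function(variants, genotypes, child, father, mother,
                            catalog, config, tier, cohort_samples) {
  trio_all <- trio_genotype_table(genotypes, child, father, mother)

  # dominant path: stringent filters 1-4, de novo call, tier restriction
  dom <- apply_stringent_filters(variants, genotypes, child, "trio_denovo",
                                 catalog, config, cohort_samples)
  dom <- filter_gene_tier(dom, catalog, tier)
  trio_dom <- trio_all[match(dom$variant_id, trio_all$variant_id), , drop = FALSE]
  dn <- dom[call_de_novo(trio_dom, config$min_depth), , drop = FALSE]
  dn_trio <- trio_all[match(dn$variant_id, trio_all$variant_id), , drop = FALSE]
  dn_out <- dn |>
    mutate(sample_id = child,
           inheritance_pattern = dplyr::if_else(dn_trio$gt_child == "hemi_alt",
                                                "hemizygous", "de_novo_het"),
           model = dplyr::if_else(dn_trio$gt_child == "hemi_alt", "XLR", "AD"),
           parent_of_origin = "none",
           partner_id = NA_character_, pair_id = NA_character_)

  # recessive path: non-silent + stringent 1-3, per-gene recessive calling
  rec <- select_nonsilent(variants, config)
  rec <- apply_stringent_filters(rec, genotypes, child, "trio_recessive",
                                 catalog, config, cohort_samples)
  rec <- filter_gene_tier(rec, catalog, tier)
  rec_ok <- catalog_gene_has_model(catalog, rec$gene, c("AR", "XLR")) |
    !catalog_gene_has_model(catalog, rec$gene,
                            c("AD", "AR", "XLR", "XLD")) # unknown model
  rec <- rec[rec_ok & !is.na(rec$gene), , drop = FALSE]
  rec_calls <- rec |>
    group_by(.data$gene) |>
    group_modify(function(d, key) {
      tr <- trio_all[match(d$variant_id, trio_all$variant_id), , drop = FALSE]
      call_recessive(tr)
    }) |>
    ungroup()
  rec_out <- rec |>
    inner_join(rec_calls, by = c("variant_id", "gene")) |>
    mutate(sample_id = child,
           inheritance_pattern = .data$pattern,
           model = dplyr::if_else(.data$pattern == "hemizygous", "XLR", "AR"),
           pair_id = dplyr::if_else(is.na(.data$pair_id), NA_character_,
                            paste(child, .data$gene, .data$pair_id,
                                  sep = ":"))) |>
    select(-"pattern")

  dplyr::bind_rows(dn_out, rec_out) |>
    distinct(.data$variant_id, .data$pair_id, .keep_all = TRUE)
}

empty_candidates <- function() {
  tibble(sample_id = character(), variant_id = character(),
         chrom = character(), pos = integer(), ref = character(),
         alt = character(), gene = character(), tier = character(),
         inheritance_pattern = character(), model = character(),
         parent_of_origin = character(), classification = character(),
         ref_depth = integer(), alt_depth = integer(),
         partner_id = character(), pair_id = character())
}

# Normalize a candidate table to the standard column set/order.
candidate_columns <- function(x) {
  cols <- colnames(empty_candidates())
  for (col in setdiff(cols, colnames(x))) x[[col]] <- NA
  x[, cols, drop = FALSE]
}

# Attach proband depths, ACMG class and top tier to a candidate skeleton.
finalize_candidates <- function(cand, genotypes, catalog) {
  if (nrow(cand) == 0) return(empty_candidates())
  own <- genotypes |>
    select("variant_id", "sample_id", cand_ref = "ref_depth",
           cand_alt = "alt_depth")
  cand |>
    left_join(own, by = c("variant_id", "sample_id")) |>
    mutate(ref_depth = .data$cand_ref, alt_depth = .data$cand_alt,
           tier = catalog_top_tier(catalog, .data$gene),
           classification = .data$acmg_class) |>
    candidate_columns()
}

#' Screen singleton patients under the stringent dominant model
#'
#' Applies the full stringent filter set (1-5) plus non-silent selection and
#' the queried gene tier to each singleton patient; survivors are reported
#' as heterozygous dominant candidates.
#'
#' @inheritParams screen_trio
#' @return A candidate tibble in the same shape as [screen_trio()].
#' @export
screen_singletons <- function(variants, genotypes, pedigree, catalog,
                              config = filter_config(), tier = "S") {
  singles <- pedigree |> filter(.data$role == "singleton", .data$affected)
  all_samples <- pedigree$sample_id
  out <- purrr::map(singles$sample_id, function(s) {
    v <- select_nonsilent(variants, config)
    v <- apply_stringent_filters(v, genotypes, s, "singleton_dominant",
                                 catalog, config, all_samples)
    v <- filter_gene_tier(v, catalog, tier)
    if (nrow(v) == 0) return(NULL)
    v |> mutate(sample_id = s,
                inheritance_pattern = "het_dominant",
                model = "AD", parent_of_origin = "unknown",
                partner_id = NA_character_, pair_id = NA_character_)
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0) return(empty_candidates())
  finalize_candidates(out, genotypes, catalog) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)
}
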