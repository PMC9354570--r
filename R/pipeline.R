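# End-to-end orchestration: simulate/read -> first-pass cascade -> trio and
# singleton screening -> CNV consensus -> reports. Stages run in a fixed
# order; the SNV and CNV branches share no state.

check_paths_exist <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("input file(s) not found: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Run the full prioritization pipeline on a cohort file bundle
#'
#' Reads the cohort, applies the first-pass cascade (cohort genotyping rate,
#' repeat/segmental-duplication exclusion), screens trios (de novo and
#' recessive paths) and singletons (stringent dominant path), summarizes
#' diagnostic yield, and -- when CNV call sets are supplied -- runs the
#' dual-caller deletion consensus. Optionally writes TSV reports.
#'
#' @param vcf,ped,annotations Paths to the cohort VCF, PED and annotation
#'   TSV.
#' @param gene_sets Character vector of gene-set TSV paths.
#' @param region_beds Character vector of repeat/segdup BED paths (may be
#'   empty).
#' @param cnv_manta,cnv_canvas,cnv_exclusion,cnv_morbid_genes,
#'   cnv_pathogenic,cnv_pli Optional CNV branch inputs (all or none of the
#'   first three).
#' @param config A [filter_config()].
#' @param cnv_config A [consensus_config()].
#' @param tier Cumulative gene tier for candidate reporting (default
#'   `"S"`).
#' @param promote Optional tibble (`sample_id`, `variant_id`) of
#'   analyst-promoted VUS candidates counted in the any-candidate yield.
#' @param out_dir Optional directory for TSV reports (`candidates.tsv`,
#'   `summary.tsv`, `funnel.tsv`, `cnv_deletions.tsv`).
#' @return A list of class `pipeline_result`: `candidates`, `summary`,
#'   `funnel` (per-sample stringent traces plus the cohort first-pass
#'   trace), `tier_counts`, `cnv` (or `NULL`), `cohort`.
#' @export
run_pipeline <- function(vcf, ped, annotations, gene_sets, region_beds = character(),
                         cnv_manta = NULL, cnv_canvas = NULL,
                         cnv_exclusion = NULL, cnv_morbid_genes = NULL,
                         cnv_pathogenic = NULL, cnv_pli = NULL,
                         config = filter_config(),
                         cnv_config = consensus_config(),
                         tier = "S", promote = NULL, out_dir = NULL) {
  check_paths_exist(c(vcf, ped, annotations, gene_sets, region_beds,
                      cnv_manta, cnv_canvas, cnv_exclusion,
                      cnv_morbid_genes, cnv_pathogenic, cnv_pli))
  cohort <- read_cohort(vcf, ped)
  catalog <- read_gene_sets(gene_sets)
  ann <- read_annotations(annotations)
  variants <- annotate_variants(cohort$variants, ann)
  regions <- purrr::map(region_beds, read_regions) |> list_rbind()
  if (is.null(regions) || nrow(regions) == 0) {
    regions <- tibble(chrom = character(), start = integer(),
                      end = integer(), label = character())
  }

  # first-pass cohort-wide cascade
  base <- variants |>
    filter_genotyped_fraction(cohort$genotypes, cohort$pedigree$sample_id,
                              config$min_genotyped_fraction_step1) |>
    filter_repeat_segdup(regions)
  cohort_trace <- filter_trace(base)

  trio_cand <- screen_trio(base, cohort$genotypes, cohort$pedigree, catalog,
                           config, tier)
  single_cand <- screen_singletons(base, cohort$genotypes, cohort$pedigree,
                                   catalog, config, tier)
  candidates <- dplyr::bind_rows(trio_cand, single_cand) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)
  candidates$promoted <- FALSE
  if (!is.null(promote) && nrow(promote) > 0) {
    key <- paste(promote$sample_id, promote$variant_id)
    candidates$promoted <- paste(candidates$sample_id,
                                 candidates$variant_id) %in% key
  }
  summary <- summarize_cohort(candidates, cohort$pedigree)

  af_zero <- filter_af_zero(base, config$af_zero_databases)
  patients <- cohort$pedigree$sample_id[cohort$pedigree$affected]
  dn_ids <- candidates |>
    filter(.data$inheritance_pattern %in% c("de_novo_het")) |>
    select("variant_id", "sample_id")
  tier_counts <- tier_count_matrix(af_zero, cohort$genotypes, catalog,
                                   patients, dn_ids)

  cnv <- NULL
  if (!is.null(cnv_manta) && !is.null(cnv_canvas)) {
    calls <- dplyr::bind_rows(read_cnv_tsv(cnv_manta),
                              read_cnv_tsv(cnv_canvas))
    excl <- if (!is.null(cnv_exclusion)) {
      read_regions(cnv_exclusion, "exclusion")
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             label = character())
    }
    morbid <- if (!is.null(cnv_morbid_genes)) {
      read_regions(cnv_morbid_genes, merge = FALSE)
    } else NULL
    patho <- if (!is.null(cnv_pathogenic)) {
      read_regions(cnv_pathogenic, merge = FALSE)
    } else NULL
    pli <- if (!is.null(cnv_pli)) {
      readr::read_tsv(cnv_pli, show_col_types = FALSE)
    } else NULL
    cnv <- cnv_consensus(calls, excl, morbid, patho, pli, cnv_config)
  }

  result <- structure(
    list(candidates = candidates, summary = summary, funnel = cohort_trace,
         tier_counts = tier_counts, cnv = cnv, cohort = cohort),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_candidate_table(result$candidates,
                        file.path(out_dir, "candidates.tsv"))
  readr::write_tsv(tibble::as_tibble(result$summary),
                   file.path(out_dir, "summary.tsv"))
  readr::write_tsv(tibble::as_tibble(result$funnel),
                   file.path(out_dir, "funnel.tsv"))
  if (!is.null(result$cnv)) {
    dels <- result$cnv$deletions
    for (col in c("gene_hits", "pathogenic_region_hits")) {
      if (col %in% colnames(dels)) {
        dels[[col]] <- map_chr(dels[[col]], paste, collapse = ",")
      }
    }
    readr::write_tsv(dels, file.path(out_dir, "cnv_deletions.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d candidate variant(s) in %d patient(s)\n",
              nrow(x$candidates), dplyr::n_distinct(x$candidates$sample_id)))
  print(x$summary)
  invisible(x)
}

#' Tidy the candidate table of a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The candidate tibble, one row per candidate variant.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$candidates

#' One-row cohort-level summary of a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The [summarize_cohort()] one-row tibble.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) tibble::as_tibble(x$summary)

#' Funnel plot of a pipeline result's first-pass cascade
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot funnel of the cohort-wide filtration trace.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  autoplot(object$funnel)
}
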