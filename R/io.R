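# Readers and writers for the cohort's standard formats: multi-sample VCF
# (via vcfR), 6-column PED, annotation TSV, gene-set TSV, and CNV call sets
# (TSV or SV-VCF). All genomic readers normalize the "chr" prefix.

#' Read a 6-column pedigree (PED) file
#'
#' Whitespace-delimited PED: family, sample, father, mother, sex (1 = male,
#' 2 = female), phenotype (2 = affected). `0` parent ids become `NA`. A sample
#' is classed as a trio proband only when both parents are present in the
#' file; affected samples with incomplete parental data are singletons.
#'
#' @param path Path to a PED file.
#' @return A tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`, `role` (one of `"trio_proband"`,
#'   `"parent"`, `"singleton"`).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  ped <- as_tibble(raw) |>
    mutate(
      father_id = ifelse(.data$father_id == "0", NA_character_, .data$father_id),
      mother_id = ifelse(.data$mother_id == "0", NA_character_, .data$mother_id),
      sex = dplyr::case_match(.data$sex, "1" ~ "male", "2" ~ "female",
                              .default = NA_character_),
      affected = .data$phenotype == "2"
    ) |>
    select(-"phenotype")
  if (anyDuplicated(ped$sample_id)) {
    abort("duplicated sample ids in PED file")
  }
  check_no_ancestor_cycle(ped)
  ped |> mutate(role = pedigree_roles(ped))
}

pedigree_roles <- function(ped) {
  is_parent <- ped$sample_id %in% c(ped$father_id, ped$mother_id)
  is_trio <- !is.na(ped$father_id) & !is.na(ped$mother_id) &
    ped$father_id %in% ped$sample_id & ped$mother_id %in% ped$sample_id
  dplyr::case_when(is_trio ~ "trio_proband",
                   is_parent ~ "parent",
                   .default = "singleton")
}

check_no_ancestor_cycle <- function(ped) {
  parent_of <- function(s) {
    i <- match(s, ped$sample_id)
    c(ped$father_id[i], ped$mother_id[i])
  }
  for (s in ped$sample_id) {
    seen <- character()
    frontier <- s
    while (length(frontier) > 0) {
      anc <- stats::na.omit(unlist(lapply(frontier, parent_of)))
      anc <- anc[anc %in% ped$sample_id]
      if (s %in% anc) abort(sprintf("sample %s is its own ancestor", s))
      frontier <- setdiff(anc, seen)
      seen <- union(seen, anc)
    }
  }
  invisible(TRUE)
}

#' Read a multi-sample VCF and pedigree into cohort tables
#'
#' Reads SNV/indel calls with vcfR, decomposes multi-allelic sites into one
#' record per ALT allele, and normalizes genotypes. Male chrX calls outside
#' the (configurable) pseudo-autosomal regions are mapped to hemizygous
#' states. Allele depths come from the AD FORMAT field; a missing AD with a
#' present DP is accepted as `DP,0` for hom-ref calls only.
#'
#' @param vcf_path Path to a VCF 4.2 file (plain or gzipped).
#' @param ped_path Path to the matching PED file; every PED sample must have
#'   a genotype column in the VCF.
#' @param par_regions Optional interval table ([read_regions()]) of chrX
#'   pseudo-autosomal regions kept diploid in males; default none.
#' @return A list of class `cohort` with elements `variants` (one row per
#'   decomposed variant: `variant_id`, `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `n_alt_site`), `genotypes` (one row per variant x sample:
#'   `variant_id`, `sample_id`, `gt`, `ref_depth`, `alt_depth`) and
#'   `pedigree`.
#' @export
read_cohort <- function(vcf_path, ped_path, par_regions = NULL) {
  ped <- read_pedigree(ped_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(ped$sample_id, vcf_samples)
  if (length(missing_samples) > 0) {
    abort(sprintf("PED sample(s) absent from VCF: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!"GT" %in% fmt) abort("VCF lacks the GT FORMAT field")
  if (!"AD" %in% fmt && !"DP" %in% fmt) {
    abort("VCF lacks both AD and DP FORMAT fields")
  }

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  chrom <- norm_chrom(fix$CHROM)
  pos <- as.integer(fix$POS)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt_site <- lengths(alts)

  # decomposition: one record per ALT allele of each site
  orig <- rep(seq_along(pos), n_alt_site)
  alt_idx <- unlist(lapply(n_alt_site, seq_len))
  variants <- tibble(
    site_id = sprintf("site%05d", orig),
    chrom = chrom[orig],
    pos = pos[orig],
    ref = toupper(fix$REF[orig]),
    alt = toupper(unlist(alts)),
    n_alt_site = n_alt_site[orig]
  ) |>
    mutate(variant_id = sprintf("%s:%d:%s>%s", .data$chrom, .data$pos,
                                .data$ref, .data$alt), .before = 1)
  if (any(variants$ref == variants$alt)) abort("REF equals ALT in a record")

  samples <- ped$sample_id
  gtm <- vcfR::extract.gt(v, "GT", return.alleles = FALSE)[, samples, drop = FALSE]
  adm <- if ("AD" %in% fmt) {
    vcfR::extract.gt(v, "AD")[, samples, drop = FALSE]
  } else {
    matrix(NA_character_, nrow(gtm), length(samples))
  }
  dpm <- if ("DP" %in% fmt) {
    suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))[, samples, drop = FALSE]
  } else {
    matrix(NA_real_, nrow(gtm), length(samples))
  }

  n_rec <- nrow(variants)
  sex <- setNames(ped$sex, ped$sample_id)
  long <- tibble(
    variant_id = rep(variants$variant_id, each = length(samples)),
    sample_id = rep(samples, times = n_rec),
    gt_str = as.vector(t(gtm[orig, , drop = FALSE])),
    ad_str = as.vector(t(adm[orig, , drop = FALSE])),
    dp = as.vector(t(dpm[orig, , drop = FALSE])),
    alt_idx = rep(alt_idx, each = length(samples)),
    chrom = rep(variants$chrom, each = length(samples)),
    pos = rep(variants$pos, each = length(samples))
  )
  in_par <- if (is.null(par_regions) || nrow(par_regions) == 0) {
    rep(FALSE, nrow(long))
  } else {
    points_in_regions(long$chrom, long$pos, par_regions)
  }
  hemi <- is_chrx(long$chrom) & sex[long$sample_id] == "male" & !in_par
  gt <- normalize_gt(long$gt_str, long$alt_idx, hemi)
  depths <- parse_ad(long$ad_str, long$alt_idx, gt, long$dp)
  genotypes <- long |>
    mutate(gt = gt, ref_depth = depths$ref_depth,
           alt_depth = depths$alt_depth) |>
    select("variant_id", "sample_id", "gt", "ref_depth", "alt_depth")

  structure(list(variants = variants, genotypes = genotypes, pedigree = ped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d variants x %d samples (%d trio probands, %d singletons)\n",
              nrow(x$variants), nrow(x$pedigree),
              sum(x$pedigree$role == "trio_proband"),
              sum(x$pedigree$role == "singleton")))
  invisible(x)
}

#' Write cohort variant and genotype tables to a VCF 4.2 file
#'
#' Plain-text writer producing one line per (already decomposed) variant
#' record with GT:AD per sample; hemizygous calls are written haploid.
#' Re-reading with [read_cohort()] reproduces chrom/pos/ref/alt and all
#' genotype states and depths.
#'
#' @param variants,genotypes Cohort tables as returned by [read_cohort()].
#' @param samples Character vector fixing the sample column order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, genotypes, samples, path) {
  gt_txt <- genotypes |>
    mutate(
      gts = dplyr::case_match(.data$gt,
        "hom_ref" ~ "0/0", "het" ~ "0/1", "hom_alt" ~ "1/1",
        "hemi_ref" ~ "0", "hemi_alt" ~ "1", "missing" ~ "./."),
      ads = ifelse(.data$gt == "missing" | is.na(.data$ref_depth), ".",
                   paste0(.data$ref_depth, ",", .data$alt_depth)),
      cell = paste0(.data$gts, ":", .data$ads)
    ) |>
    select("variant_id", "sample_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell",
                       values_fill = "./.:.")
  ord <- variants |> arrange(.data$chrom, .data$pos, .data$alt)
  gt_txt <- gt_txt[match(ord$variant_id, gt_txt$variant_id), , drop = FALSE]
  missing_cols <- setdiff(samples, colnames(gt_txt))
  for (s in missing_cols) gt_txt[[s]] <- "./.:."
  body <- paste(ord$chrom, ord$pos, ".", ord$ref, ord$alt, ".", "PASS", ".",
                "GT:AD",
                do.call(paste, c(unname(as.list(gt_txt[, samples, drop = FALSE])),
                                 list(sep = "\t"))),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(ord$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Tab-separated with a header; keyed by `chrom`, `pos`, `ref`, `alt`.
#' Allele-frequency columns are named `af_<database>` (defaults:
#' `r paste0("af_", AF_DATABASES, collapse = ", ")`); an empty/NA cell means
#' the variant is absent from that database, which is distinct from a stored
#' numeric 0 but treated as frequency zero by the filters.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with the key columns plus `gene`, `consequence`,
#'   `af_*`, `cadd`, `rf_score`, `ada_score`, `cadd_splice_flag`,
#'   `acmg_class`, `clinvar_reported`, `in_repeat_or_segdup`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(
    path, show_col_types = FALSE, na = c("", "NA", "."),
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", gene = "c",
      consequence = "c", acmg_class = "c", cadd_splice_flag = "l",
      clinvar_reported = "l", in_repeat_or_segdup = "l", .default = "d"))
  ann$chrom <- norm_chrom(ann$chrom)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(need, colnames(ann))
  if (length(miss) > 0) {
    abort(sprintf("annotation table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  bad <- setdiff(ann$consequence[!is.na(ann$consequence)], CONSEQUENCES)
  if (length(bad) > 0) {
    abort(sprintf("unknown consequence value(s): %s", paste(bad, collapse = ", ")))
  }
  ann
}

# Consequence vocabulary; the first six are the non-silent classes.
CONSEQUENCES <- c("nonsynonymous_snv", "stopgain", "stoploss",
                  "frameshift_indel", "inframe_indel", "canonical_splice",
                  "synonymous", "utr", "intronic", "intergenic")
NONSILENT_CONSEQUENCES <- CONSEQUENCES[1:6]

# Default allele-frequency database registry.
AF_DATABASES <- c("gnomad_v2", "gnomad_v3", "kaviar", "krgdb", "togovar",
                  "inhouse")

#' Join annotations onto a variant table
#'
#' Left-joins by `chrom`/`pos`/`ref`/`alt` and fills conservative defaults
#' for unannotated records (intergenic, unclassified, no flags).
#'
#' @param variants Variant table ([read_cohort()]).
#' @param annotations Annotation table ([read_annotations()]).
#' @return The variant tibble with annotation columns appended.
#' @export
annotate_variants <- function(variants, annotations) {
  defaults <- list(gene = NA_character_, consequence = NA_character_,
                   acmg_class = NA_character_, cadd_splice_flag = NA,
                   clinvar_reported = NA, in_repeat_or_segdup = NA)
  for (nm in names(defaults)) {
    if (!nm %in% colnames(annotations)) annotations[[nm]] <- defaults[[nm]]
  }
  out <- variants |>
    left_join(annotations, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(
      consequence = dplyr::coalesce(.data$consequence, "intergenic"),
      acmg_class = dplyr::coalesce(.data$acmg_class, "unclassified"),
      cadd_splice_flag = dplyr::coalesce(.data$cadd_splice_flag, FALSE),
      clinvar_reported = dplyr::coalesce(.data$clinvar_reported, FALSE),
      in_repeat_or_segdup = dplyr::coalesce(.data$in_repeat_or_segdup, FALSE)
    )
  for (db in paste0("af_", AF_DATABASES)) {
    if (!db %in% colnames(out)) out[[db]] <- NA_real_
  }
  for (col in c("cadd", "rf_score", "ada_score")) {
    if (!col %in% colnames(out)) out[[col]] <- NA_real_
  }
  out
}

# Gene tiers, most specific first: curated epilepsy (E), seizure-associated
# (S), morbid OMIM (O). A tier query is cumulative: S means E+S, O means all.
TIERS <- c("E", "S", "O")
INHERITANCE_MODELS <- c("AD", "AR", "XLR", "XLD")

#' Read gene-set tables into a gene catalog
#'
#' Each TSV row is `gene`, `tier` (E/S/O), `inheritance` (comma-separated
#' subset of AD/AR/XLR/XLD, possibly empty). Genes listed in several files
#' accumulate tiers and models.
#'
#' @param paths One or more gene-set TSV paths.
#' @return A tibble of class `gene_catalog`: `gene`, list-columns `tiers`
#'   and `models`.
#' @export
read_gene_sets <- function(paths) {
  rows <- purrr::map(paths, function(p) {
    readr::read_tsv(p, show_col_types = FALSE, na = c("", "NA"),
                    col_types = readr::cols(.default = "c"))
  }) |> list_rbind()
  bad <- setdiff(rows$tier, TIERS)
  if (length(bad) > 0) {
    abort(sprintf("unknown gene tier code(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"inheritance" %in% colnames(rows)) rows$inheritance <- NA_character_
  models <- strsplit(ifelse(is.na(rows$inheritance), "", rows$inheritance),
                     "[,;|]")
  bad <- setdiff(unlist(models), c(INHERITANCE_MODELS, ""))
  if (length(bad) > 0) {
    abort(sprintf("unknown inheritance model(s): %s", paste(bad, collapse = ", ")))
  }
  cat <- tibble(gene = rows$gene, tier = rows$tier, models = models) |>
    group_by(.data$gene) |>
    summarise(tiers = list(sort(unique(.data$tier))),
              models = list(sort(setdiff(unique(unlist(.data$models)), ""))),
              .groups = "drop")
  structure(cat, class = c("gene_catalog", class(cat)))
}

# Cumulative tier set for a query tier: E -> E; S -> E,S; O -> E,S,O; any -> all.
cumulative_tiers <- function(tier) {
  if (identical(tier, "any")) return(TIERS)
  if (!tier %in% TIERS) abort(sprintf("unknown tier query '%s'", tier))
  TIERS[seq_len(match(tier, TIERS))]
}

# Highest (most specific) tier of each gene; NA for genes not in the catalog.
catalog_top_tier <- function(catalog, genes) {
  i <- match(genes, catalog$gene)
  map_chr(seq_along(genes), function(k) {
    if (is.na(i[k])) return(NA_character_)
    t <- catalog$tiers[[i[k]]]
    TIERS[min(match(t, TIERS))]
  })
}

# Does each gene fall in the cumulative set of `tier`?
catalog_gene_in_tier <- function(catalog, genes, tier) {
  keep <- cumulative_tiers(tier)
  i <- match(genes, catalog$gene)
  map_lgl(seq_along(genes), function(k) {
    !is.na(i[k]) && length(intersect(catalog$tiers[[i[k]]], keep)) > 0
  })
}

# Does each gene carry any of the given inheritance models?
catalog_gene_has_model <- function(catalog, genes, models) {
  i <- match(genes, catalog$gene)
  map_lgl(seq_along(genes), function(k) {
    !is.na(i[k]) && length(intersect(catalog$models[[i[k]]], models)) > 0
  })
}

#' Read a CNV deletion call set from a TSV file
#'
#' Expects columns `caller`, `sample_id`, `chrom`, `start`, `end` (0-based
#' half-open), `filter`, `qual`, `imprecise`.
#'
#' @param path Path to the call-set TSV.
#' @return A tibble of deletion calls with one `call_id` per row.
#' @export
read_cnv_tsv <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  calls |>
    mutate(chrom = norm_chrom(.data$chrom),
           start = as.integer(.data$start), end = as.integer(.data$end),
           imprecise = as.logical(.data$imprecise),
           qual = as.numeric(.data$qual),
           call_id = sprintf("%s_%s_%05d", .data$caller, .data$sample_id,
                             dplyr::row_number()))
}

#' Read deletion calls from an SV-VCF (Manta/Canvas style)
#'
#' Keeps records with `SVTYPE=DEL`; the deletion interval is taken as
#' `[POS, END)` in 0-based half-open coordinates using the INFO `END` tag.
#' In a multi-sample (joint) VCF, a call is assigned to every sample whose
#' genotype carries the alternate allele.
#'
#' @param path Path to the SV-VCF.
#' @param caller Caller name recorded on each call (e.g. `"manta"`).
#' @return A tibble in the same shape as [read_cnv_tsv()].
#' @export
read_sv_vcf <- function(path, caller) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  svtype <- sub(".*SVTYPE=([^;]+).*", "\\1",
                ifelse(grepl("SVTYPE=", info), info, "SVTYPE=NA"))
  keep <- which(svtype == "DEL")
  if (length(keep) == 0) {
    return(tibble(caller = character(), sample_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  filter = character(), qual = numeric(),
                  imprecise = logical(), call_id = character()))
  }
  endv <- suppressWarnings(as.integer(
    sub(".*(?:^|;)END=([0-9]+).*", "\\1", info[keep])))
  gtm <- vcfR::extract.gt(v, "GT")[keep, , drop = FALSE]
  carried <- !is.na(gtm) & grepl("1", gtm)
  rows <- which(carried, arr.ind = TRUE)
  tibble(
    caller = caller,
    sample_id = colnames(gtm)[rows[, "col"]],
    chrom = norm_chrom(fix$CHROM[keep][rows[, "row"]]),
    start = as.integer(fix$POS[keep][rows[, "row"]]),
    end = endv[rows[, "row"]],
    filter = fix$FILTER[keep][rows[, "row"]],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep][rows[, "row"]])),
    imprecise = grepl("(^|;)IMPRECISE(;|$)", info[keep][rows[, "row"]])
  ) |>
    arrange(.data$sample_id, .data$chrom, .data$start) |>
    mutate(call_id = sprintf("%s_%s_%05d", caller, .data$sample_id,
                             dplyr::row_number()))
}
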