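# Seeded synthetic cohort generator. Produces a fully self-contained file
# bundle -- multi-sample VCF, PED, annotation TSV, gene-set TSVs, region
# BEDs, dual-caller CNV call sets, and ground-truth tables -- emulating a
# small rare-disease WGS cohort of parent-child trios and singletons with
# planted causal variants of every inheritance class the screen detects.
#
# Background variants are deliberately confined to silent/non-coding
# consequences: the non-coding bulk of private variation is what a genome
# screen wades through, and it keeps planted sensitivity and precision
# well-defined (see the methods vignette).

SYNTH_GENOME <- tibble::tibble(
  chrom = c("chr1", "chr2", "chrX"),
  length = c(120e6, 100e6, 60e6)
)

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study layout this package targets: 6 trios plus
#' 10 singletons (28 genomes), mean coverage depth 60x, and one planted
#' causal variant per inheritance class (de novo stopgain, in-trans
#' compound-het pair, deep-intronic de novo, X-linked hemizygous splice,
#' and two singleton dominant hits).
#'
#' @param n_trios,n_singletons Cohort layout (defaults 6 and 10).
#' @param n_background_variants Background variant sites cohort-wide
#'   (default 5000).
#' @param af_spectrum Mixture weights over allele-frequency bins
#'   `common` (>= 0.01), `low` (0.001-0.01), `rare` (1e-5-0.001) and
#'   `absent` (unobserved in every database).
#' @param mean_depth Mean sequencing depth (default 60).
#' @param missing_genotype_rate Baseline per-genotype missingness
#'   (default 0.02); a small fraction of sites
#'   (`high_missing_site_fraction`) is poorly genotyped (rate 0.6) to feed
#'   the genotyping-rate filter.
#' @param high_missing_site_fraction Fraction of badly genotyped sites
#'   (default 0.05).
#' @param multiallelic_site_fraction Fraction of background sites emitted
#'   with two ALT alleles (default 0.03).
#' @param overcalled_sample Sample whose Canvas call count is inflated
#'   (default `"IS16"`).
#' @param overcalled_sample_factor Inflation multiple (default 5).
#' @param manta_mean_calls,canvas_mean_calls Mean background deletion calls
#'   per sample and caller (defaults 40 and 12).
#' @param breakpoint_jitter_fraction Per-caller breakpoint jitter of planted
#'   dual-caller deletions, as a fraction of the deletion length (default
#'   0.1; any value <= 0.15 preserves reciprocal overlap >= 0.7).
#' @param plants Planted-variant table (see `default_plants()` in the
#'   package sources); one row per planted allele with its host gene,
#'   consequence, depth profile and expected classification.
#' @param seed Integer seed; the bundle is byte-identical given a seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_trios = 6, n_singletons = 10,
                        n_background_variants = 5000,
                        af_spectrum = c(common = 0.45, low = 0.25,
                                        rare = 0.20, absent = 0.10),
                        mean_depth = 60,
                        missing_genotype_rate = 0.02,
                        high_missing_site_fraction = 0.05,
                        multiallelic_site_fraction = 0.03,
                        overcalled_sample = "IS16",
                        overcalled_sample_factor = 5,
                        manta_mean_calls = 40,
                        canvas_mean_calls = 12,
                        breakpoint_jitter_fraction = 0.1,
                        plants = default_plants(),
                        seed = 1L) {
  stopifnot(abs(sum(af_spectrum) - 1) < 1e-8,
            all(names(af_spectrum) == c("common", "low", "rare", "absent")))
  structure(as.list(environment()), class = "cohort_spec")
}

# Sample ids: trio probands IS01..IS0k with _fa/_mo parents, then singletons.
spec_samples <- function(spec) {
  probands <- sprintf("IS%02d", seq_len(spec$n_trios))
  singletons <- sprintf("IS%02d", spec$n_trios + seq_len(spec$n_singletons))
  ped <- dplyr::bind_rows(
    tibble(family_id = probands, sample_id = probands,
           father_id = paste0(probands, "_fa"),
           mother_id = paste0(probands, "_mo"),
           # proband sexes alternate; the hemizygous plant host (IS06) is male
           sex = rep(c("male", "female"), length.out = spec$n_trios),
           affected = TRUE),
    tibble(family_id = probands, sample_id = paste0(probands, "_fa"),
           father_id = NA, mother_id = NA, sex = "male", affected = FALSE),
    tibble(family_id = probands, sample_id = paste0(probands, "_mo"),
           father_id = NA, mother_id = NA, sex = "female", affected = FALSE),
    tibble(family_id = singletons, sample_id = singletons,
           father_id = NA, mother_id = NA,
           sex = rep(c("female", "male"), length.out = spec$n_singletons),
           affected = TRUE)
  )
  ped$sex[ped$sample_id == "IS06"] <- "male"
  ped
}

# Deterministic gene catalog: curated-epilepsy (EPG), seizure-associated
# (SZG) and morbid-OMIM (OMG) genes laid head-to-tail with gaps. The last
# few SZG/OMG genes live on chrX with an X-linked model.
synth_genes <- function() {
  gene_len <- 5e4
  gap <- 8e5
  mk <- function(prefix, n, tier) {
    tibble(gene = sprintf("%s%02d", prefix, seq_len(n)), tier = tier)
  }
  genes <- dplyr::bind_rows(mk("EPG", 10, "E"), mk("SZG", 50, "S"),
                            mk("OMG", 99, "O"))
  n <- nrow(genes)
  on_x <- genes$gene %in% c("SZG49", "SZG50", "OMG98", "OMG99")
  auto <- genes[!on_x, ]
  half <- ceiling(nrow(auto) / 2)
  place <- function(d, chrom, offset = 5e6) {
    d |> mutate(chrom = chrom,
                start = offset + (dplyr::row_number() - 1L) * (gene_len + gap),
                end = .data$start + gene_len)
  }
  placed <- dplyr::bind_rows(
    place(auto[seq_len(half), ], "chr1"),
    place(auto[-seq_len(half), ], "chr2"),
    place(genes[on_x, ], "chrX")
  )
  models <- dplyr::case_when(
    placed$chrom == "chrX" ~ "XLR",
    placed$gene %in% c("SZG01", "EPG09") ~ "AR",
    substr(placed$gene, 1, 3) == "OMG" &
      as.integer(substr(placed$gene, 4, 5)) %% 3 == 0 ~ "AR",
    substr(placed$gene, 4, 5) >= "90" ~ "",  # unknown model
    .default = "AD"
  )
  placed |> mutate(inheritance = models, start = as.integer(.data$start),
                   end = as.integer(.data$end))
}

# Default planted variant set, one per inheritance class.
default_plants <- function() {
  tibble::tribble(
    ~sample, ~pattern, ~gene, ~consequence, ~ref_depth, ~alt_depth,
    ~acmg, ~cadd, ~promoted, ~partner_slot,
    "IS01", "de_novo_het", "EPG01", "stopgain", 28L, 32L, "P", 42.0, FALSE, NA,
    "IS02", "compound_het_pair", "SZG01", "nonsynonymous_snv", 36L, 33L, "LP", 26.7, FALSE, "a",
    "IS02", "compound_het_pair", "SZG01", "nonsynonymous_snv", 32L, 31L, "LP", 25.8, FALSE, "b",
    "IS05", "de_novo_het", "SZG02", "intronic", 29L, 28L, "VUS", 17.9, TRUE, NA,
    "IS06", "hemizygous", "SZG50", "intronic", 0L, 38L, "VUS", 21.2, TRUE, NA,
    "IS11", "het_dominant", "EPG02", "nonsynonymous_snv", 38L, 34L, "LP", 24.1, FALSE, NA,
    "IS15", "het_dominant", "SZG03", "stopgain", 36L, 35L, "P", 39.0, FALSE, NA
  )
}

# Repeat/segdup masks: 500-kb tiles of non-gene space, a bit over half of
# which are masked, split between the two files; together they cover about
# 45% of the genome, so the region filter dominates the first-pass removal.
synth_region_masks <- function(genes) {
  tiles <- SYNTH_GENOME |>
    rowwise() |>
    reframe(chrom = .data$chrom,
            start = as.integer(seq(0, .data$length - 5e5, by = 5e5))) |>
    mutate(end = .data$start + 5e5L)
  hit_gene <- intervals_overlap_any(tiles, genes |> select("chrom", "start", "end"))
  free <- tiles[!hit_gene, ]
  pick <- seq_len(nrow(free)) %% 9
  list(repeats = free[pick %in% c(0, 1, 3), ] |> mutate(label = "repeat"),
       segdups = free[pick %in% c(5, 7), ] |> mutate(label = "segdup"))
}

draw_af <- function(bin) {
  switch(bin,
         common = runif(1, 0.01, 0.5),
         low = runif(1, 0.001, 0.01),
         rare = 10^runif(1, -5, -3),
         absent = 0)
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic cohort file bundle
#'
#' Writes a multi-sample VCF (background variants with Mendelian-consistent
#' trio genotypes plus the planted causal set), PED, annotation TSV,
#' per-tier gene-set TSVs, repeat and segmental-duplication BED masks, and
#' a truth table recording every planted variant with its expected verdict.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `paths` (named file paths) and `truth` (planted
#'   variant tibble), invisibly classed `cohort_bundle`.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  ped <- spec_samples(spec)
  samples <- ped$sample_id
  genes <- synth_genes()
  masks <- synth_region_masks(genes)
  sex <- setNames(ped$sex, samples)

  # ---- background sites ----
  n_bg <- spec$n_background_variants
  bins <- sample(names(spec$af_spectrum), n_bg, replace = TRUE,
                 prob = spec$af_spectrum)
  in_gene <- runif(n_bg) < 0.55
  gene_idx <- sample.int(nrow(genes), n_bg, replace = TRUE)
  gene_sym <- ifelse(in_gene, genes$gene[gene_idx], NA_character_)
  chrom <- ifelse(in_gene, genes$chrom[gene_idx],
                  sample(SYNTH_GENOME$chrom, n_bg, replace = TRUE,
                         prob = SYNTH_GENOME$length))
  pos <- ifelse(in_gene,
                genes$start[gene_idx] +
                  sample.int(5e4 - 1L, n_bg, replace = TRUE),
                floor(runif(n_bg, 1,
                            SYNTH_GENOME$length[match(chrom,
                                                      SYNTH_GENOME$chrom)])))
  pos <- as.integer(pos)
  consequence <- ifelse(
    in_gene,
    sample(c("intronic", "utr", "synonymous"), n_bg, replace = TRUE,
           prob = c(0.75, 0.12, 0.13)),
    "intergenic")
  ref <- sample(BASES, n_bg, replace = TRUE)
  alt <- map_chr(ref, function(r) sample(setdiff(BASES, r), 1))
  base_af <- map_dbl(bins, draw_af)
  multi <- runif(n_bg) < spec$multiallelic_site_fraction

  bg <- tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
               gene = as.character(gene_sym),
               consequence = as.character(consequence), bin = as.character(bins),
               base_af = as.numeric(base_af), multi = multi,
               # cohort carrier allele frequency: database-absent variants
               # are private-but-present at low frequency
               carrier_af = as.numeric(ifelse(bins == "absent", 0.02,
                                              pmin(base_af, 0.5))),
               site_missing_rate = as.numeric(ifelse(
                 runif(n_bg) < spec$high_missing_site_fraction, 0.6,
                 spec$missing_genotype_rate))) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  bin_counts <- table(factor(bg$bin, levels = names(spec$af_spectrum)))

  # ---- founder and child genotypes (allele dosage per sample) ----
  dosage <- draw_cohort_dosages(bg, ped, sex)

  # drop sites nobody carries (a joint caller would not emit them)
  carried_site <- rowSums(dosage > 0, na.rm = TRUE) > 0
  bg <- bg[carried_site, , drop = FALSE]
  dosage <- dosage[carried_site, , drop = FALSE]

  # ---- planted variants ----
  plants <- spec$plants
  plant_rows <- plant_variants(plants, genes, ped)
  planted_dosage <- plant_rows$dosage
  bg_all <- dplyr::bind_rows(bg |> mutate(planted = FALSE),
                             plant_rows$sites |> mutate(planted = TRUE))
  dosage <- rbind(dosage, planted_dosage)
  ord <- order(match(bg_all$chrom, SYNTH_GENOME$chrom), bg_all$pos)
  bg_all <- bg_all[ord, , drop = FALSE]
  dosage <- dosage[ord, , drop = FALSE]

  # ---- depths and missingness ----
  gtdata <- draw_depths(bg_all, dosage, sex, spec)
  gtdata <- apply_plant_depths(gtdata, bg_all, plants, plant_rows$truth, ped)

  # ---- write bundle ----
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    genes_e = file.path(dir, "genes_E.tsv"),
    genes_s = file.path(dir, "genes_S.tsv"),
    genes_o = file.path(dir, "genes_O.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    segdups = file.path(dir, "segdups.bed"),
    truth = file.path(dir, "truth_variants.tsv")
  )
  write_synth_vcf(bg_all, gtdata, samples, paths$vcf)
  write_synth_ped(ped, paths$ped)
  write_synth_annotations(bg_all, masks, paths$annotations)
  write_synth_gene_sets(genes, paths)
  write_bed <- function(d, p) {
    readr::write_tsv(d |> select("chrom", "start", "end", "label"), p,
                     col_names = FALSE)
  }
  write_bed(masks$repeats, paths$repeats)
  write_bed(masks$segdups, paths$segdups)
  truth <- plant_rows$truth
  readr::write_tsv(truth, paths$truth)
  invisible(structure(list(paths = paths, truth = truth, spec = spec,
                           bin_counts = bin_counts),
                      class = "cohort_bundle"))
}

# Dosage matrix (sites x samples): founders from the carrier allele
# frequency (Hardy-Weinberg; haploid on male chrX), children by Mendelian
# transmission from their parents.
draw_cohort_dosages <- function(bg, ped, sex) {
  n <- nrow(bg)
  samples <- ped$sample_id
  dosage <- matrix(0L, n, length(samples),
                   dimnames = list(NULL, samples))
  x_site <- is_chrx(bg$chrom)
  founder_ids <- ped$sample_id[is.na(ped$father_id)]
  for (s in founder_ids) {
    p <- bg$carrier_af
    male_x <- x_site & sex[s] == "male"
    d <- rbinom(n, 2L, p)
    d[male_x] <- rbinom(sum(male_x), 1L, p[male_x])
    dosage[, s] <- d
  }
  transmit <- function(par_dosage, ploidy) {
    rbinom(length(par_dosage), 1L, pmin(1, par_dosage / ploidy))
  }
  kids <- ped |> filter(!is.na(.data$father_id))
  for (i in seq_len(nrow(kids))) {
    kid <- kids$sample_id[i]
    fa <- dosage[, kids$father_id[i]]
    mo <- dosage[, kids$mother_id[i]]
    fa_ploidy <- ifelse(x_site, 1L, 2L)
    from_fa <- transmit(fa, fa_ploidy)
    from_mo <- transmit(mo, 2L)
    d <- from_fa + from_mo
    if (sex[kid] == "male") d[x_site] <- from_mo[x_site]
    dosage[, kid] <- d
  }
  dosage
}

# Build planted variant sites, their dosages, and the truth table.
plant_variants <- function(plants, genes, ped) {
  samples <- ped$sample_id
  gi <- match(plants$gene, genes$gene)
  if (anyNA(gi)) abort("planted gene not present in the generated gene sets")
  offset <- 1000L + 500L * seq_len(nrow(plants))
  sites <- tibble(
    chrom = genes$chrom[gi],
    pos = genes$start[gi] + offset,
    ref = rep(c("C", "G", "A", "T"), length.out = nrow(plants)),
    alt = rep(c("T", "A", "G", "C"), length.out = nrow(plants)),
    gene = plants$gene,
    consequence = plants$consequence,
    bin = "absent", base_af = 0, multi = FALSE,
    carrier_af = 0, site_missing_rate = 0
  )
  dosage <- matrix(0L, nrow(plants), length(samples),
                   dimnames = list(NULL, samples))
  fa <- setNames(ped$father_id, ped$sample_id)
  mo <- setNames(ped$mother_id, ped$sample_id)
  for (i in seq_len(nrow(plants))) {
    s <- plants$sample[i]
    dosage[i, s] <- 1L
    if (plants$pattern[i] == "compound_het_pair") {
      parent <- if (plants$partner_slot[i] == "a") fa[s] else mo[s]
      dosage[i, parent] <- 1L
    }
    if (plants$pattern[i] == "hemizygous") {
      # maternally inherited single-copy chrX variant: het carrier mother
      dosage[i, mo[s]] <- 1L
    }
    # de novo / het_dominant: parents (if any) stay hom-ref
  }
  variant_id <- sprintf("%s:%d:%s>%s", sites$chrom, sites$pos, sites$ref,
                        sites$alt)
  truth <- tibble(
    sample_id = plants$sample,
    variant_id = variant_id,
    gene = plants$gene,
    pattern = ifelse(plants$pattern == "compound_het_pair", "compound_het",
                     plants$pattern),
    classification = plants$acmg,
    promoted = plants$promoted
  )
  list(sites = sites |> mutate(acmg = plants$acmg, cadd = plants$cadd,
                               ada_score = ifelse(plants$pattern == "hemizygous",
                                                  0.7, NA_real_)),
       dosage = dosage, truth = truth)
}

# Depths, genotype strings and AD strings for every site x sample.
draw_depths <- function(sites, dosage, sex, spec) {
  n <- nrow(sites)
  samples <- colnames(dosage)
  x_site <- is_chrx(sites$chrom)
  gt_chr <- ad_chr <- matrix("", n, length(samples),
                             dimnames = list(NULL, samples))
  planted <- sites$planted %||% rep(FALSE, n)
  for (s in samples) {
    d <- dosage[, s]
    dp <- pmax(1L, rpois(n, spec$mean_depth))
    hemi <- x_site & sex[s] == "male"
    alt_d <- integer(n)
    het <- d == 1L & !hemi
    alt_d[het] <- rbinom(sum(het), dp[het], 0.5)
    hom <- (d == 2L & !hemi) | (hemi & d >= 1L)
    alt_d[hom] <- dp[hom]
    # carriers always keep at least one supporting read
    alt_d[d > 0L & alt_d == 0L] <- 1L
    ref_d <- dp - alt_d
    miss <- runif(n) < sites$site_missing_rate
    gt <- dplyr::case_when(
      miss ~ "./.",
      hemi & d >= 1L ~ "1",
      hemi ~ "0",
      d == 0L ~ "0/0",
      d == 1L ~ "0/1",
      .default = "1/1")
    ad <- ifelse(miss, ".", paste0(ref_d, ",", alt_d))
    gt_chr[, s] <- gt
    ad_chr[, s] <- ad
  }
  # planted sites carry the designed depth profile in the target sample
  list(gt = gt_chr, ad = ad_chr)
}

# Overwrite planted rows with their designed depth profiles so the target
# sample shows the intended allele counts, whatever the Poisson draw said.
apply_plant_depths <- function(gtdata, sites, plants, truth, ped) {
  vid <- sprintf("%s:%d:%s>%s", sites$chrom, sites$pos, sites$ref, sites$alt)
  for (i in seq_len(nrow(plants))) {
    row <- match(truth$variant_id[i], vid)
    s <- plants$sample[i]
    gtdata$ad[row, s] <- paste0(plants$ref_depth[i], ",", plants$alt_depth[i])
  }
  gtdata
}

write_synth_vcf <- function(sites, gtdata, samples, path) {
  gt <- gtdata$gt
  ad <- gtdata$ad
  alt_field <- ifelse(sites$multi,
                      paste0(sites$alt, ",",
                             map_chr(seq_len(nrow(sites)), function(i)
                               sample(setdiff(BASES, c(sites$ref[i],
                                                       sites$alt[i])), 1))),
                      sites$alt)
  # multi-allelic sites carry a third AD entry (no sample carries allele 2)
  body_gt <- map_chr(seq_len(nrow(sites)), function(i) {
    cells <- paste0(gt[i, ], ":", ad[i, ],
                    ifelse(sites$multi[i] & ad[i, ] != ".", ",0", ""))
    paste(cells, collapse = "\t")
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", SYNTH_GENOME$chrom,
            SYNTH_GENOME$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, alt_field, "100",
                "PASS", ".", "GT:AD", body_gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

write_synth_ped <- function(ped, path) {
  out <- ped |>
    mutate(father_id = dplyr::coalesce(.data$father_id, "0"),
           mother_id = dplyr::coalesce(.data$mother_id, "0"),
           sex_code = ifelse(.data$sex == "male", 1L, 2L),
           phenotype = ifelse(.data$affected, 2L, 1L)) |>
    select("family_id", "sample_id", "father_id", "mother_id", "sex_code",
           "phenotype")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_synth_annotations <- function(sites, masks, path) {
  jitter_af <- function(base) {
    ifelse(base == 0, NA_real_,
           pmin(1, base * runif(length(base), 0.8, 1.2)))
  }
  mask_all <- dplyr::bind_rows(masks$repeats, masks$segdups)
  ann <- tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene, consequence = sites$consequence,
    af_gnomad_v2 = jitter_af(sites$base_af),
    af_gnomad_v3 = jitter_af(sites$base_af),
    af_kaviar = jitter_af(sites$base_af),
    af_krgdb = jitter_af(sites$base_af),
    af_togovar = jitter_af(sites$base_af),
    af_inhouse = jitter_af(sites$base_af),
    cadd = sites$cadd %||% NA_real_,
    rf_score = NA_real_,
    ada_score = sites$ada_score %||% NA_real_,
    cadd_splice_flag = FALSE,
    acmg_class = sites$acmg %||% NA_character_,
    clinvar_reported = FALSE,
    in_repeat_or_segdup = points_in_regions(sites$chrom, sites$pos, mask_all)
  )
  readr::write_tsv(ann, path, na = ".")
  invisible(path)
}

write_synth_gene_sets <- function(genes, paths) {
  for (tr in TIERS) {
    d <- genes |> filter(.data$tier == tr) |>
      select("gene", "tier", "inheritance")
    readr::write_tsv(d, paths[[paste0("genes_", tolower(tr))]])
  }
  invisible(NULL)
}

# ---- dual-caller CNV call sets ---------------------------------------------

# Fixed CNV exclusion regions (low-mappability / centromere / HLA stand-ins).
synth_cnv_exclusion <- function() {
  tibble(chrom = c("chr1", "chr2", "chrX"),
         start = as.integer(c(100e6, 80e6, 50e6)),
         end = as.integer(c(110e6, 90e6, 55e6)),
         label = c("low_mappability", "centromere", "hla"))
}

# Default planted CNV set: true deletions recovered by the consensus, plus
# caller-specific and gate-violating false calls that must be removed.
default_cnv_plants <- function() {
  tibble::tribble(
    ~sample, ~chrom, ~start, ~end, ~seen_by, ~manta_filter, ~manta_imprecise,
    ~canvas_qual, ~expected, ~reason,
    "IS03", "chr1", NA, NA, "both", "PASS", FALSE, 30,
    "kept_both", "true deletion over a high-pLI morbid gene",
    "IS12", "chr1", 1e6, 56e6, "both", "PASS", FALSE, 40,
    "removed", "common call at 55 Mb fails the <50 Mb gate",
    "IS13", "chr1", 104e6, 104.4e6, "both", "PASS", FALSE, 35,
    "removed", "common call inside an exclusion region",
    "IS07", "chr2", 10e6, 10.4e6, "manta_only", "PASS", FALSE, NA,
    "kept_manta_only", "clean PASS/precise/<1 Mb Manta-only call",
    "IS04", "chr2", 30e6, 30.3e6, "manta_only", "PASS", TRUE, NA,
    "removed", "Manta-only call flagged IMPRECISE",
    "IS08", "chr2", 50e6, 51.5e6, "manta_only", "PASS", FALSE, NA,
    "removed", "Manta-only call at 1.5 Mb fails the <1 Mb gate",
    "IS09", "chr2", 60e6, 60.5e6, "canvas_only", NA, NA, 30,
    "kept_canvas_only", "clean QUAL>=10 Canvas-only call",
    "IS10", "chr2", 70e6, 70.5e6, "canvas_only", NA, NA, 5,
    "removed", "Canvas-only call with QUAL<10"
  )
}

#' Generate dual-caller deletion call sets with planted truth
#'
#' Emits Manta- and Canvas-style deletion call tables per sample:
#' background calls at caller-typical rates and sizes, one sample whose
#' Canvas output is inflated by `overcalled_sample_factor`, and planted
#' deletions -- dual-caller calls with jittered breakpoints, clean
#' caller-specific calls, and calls designed to fail each rescue gate.
#' Also writes the CNV exclusion BED, morbid-gene BED, pathogenic-region
#' BED and pLI table the consensus stage consumes. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @return A list with `paths` and `truth` (planted CNV tibble), invisibly.
#' @export
generate_cnv_callsets <- function(spec = cohort_spec(),
                                  dir = tempfile("cnv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1009L)
  ped <- spec_samples(spec)
  samples <- ped$sample_id
  genes <- synth_genes()
  morbid <- genes |> filter(.data$tier == "O") |>
    select("chrom", "start", "end", label = "gene")
  exclusion <- synth_cnv_exclusion()

  pli <- tibble(gene = morbid$label,
                pli = round(runif(nrow(morbid)), 3))
  pli$pli[pli$gene == "OMG01"] <- 1.0

  rand_calls <- function(s, caller, n, lo, hi) {
    if (n == 0) return(NULL)
    chrom <- sample(SYNTH_GENOME$chrom, n, replace = TRUE,
                    prob = SYNTH_GENOME$length)
    len <- round(10^runif(n, lo, hi))
    start <- floor(runif(n) *
                     (SYNTH_GENOME$length[match(chrom, SYNTH_GENOME$chrom)] - len))
    filt <- if (caller == "manta") {
      sample(c("PASS", "MinGQ"), n, replace = TRUE, prob = c(0.8, 0.2))
    } else rep("PASS", n)
    qual <- if (caller == "canvas") round(runif(n, 2, 60), 1) else rep(NA_real_, n)
    imprec <- if (caller == "manta") runif(n) < 0.15 else rep(FALSE, n)
    tibble(caller = caller, sample_id = s, chrom = chrom,
           start = as.integer(start), end = as.integer(start + len),
           filter = filt, qual = qual, imprecise = imprec)
  }
  background <- purrr::map(samples, function(s) {
    n_canvas <- rpois(1, spec$canvas_mean_calls)
    if (s == spec$overcalled_sample) {
      # inflate the rate and floor the draw so the sample always exceeds
      # three times the other samples' median count, by construction
      n_canvas <- max(rpois(1, spec$overcalled_sample_factor *
                              spec$canvas_mean_calls),
                      ceiling(0.8 * spec$overcalled_sample_factor *
                                spec$canvas_mean_calls))
    }
    dplyr::bind_rows(
      rand_calls(s, "manta", rpois(1, spec$manta_mean_calls), 3, 5.5),
      rand_calls(s, "canvas", n_canvas, 4, 6))
  }) |> list_rbind()

  plants <- default_cnv_plants()
  # the true dual-caller deletion sits over the pLI-1.0 morbid gene
  host <- morbid |> filter(.data$label == "OMG01")
  plants$start[1] <- host$start[1] - 75000
  plants$end[1] <- host$end[1] + 75000

  jitter_interval <- function(start, end, f) {
    len <- end - start
    shift <- function() runif(1, -f / 2, f / 2) * len
    c(round(start + shift()), round(end + shift()))
  }
  planted_calls <- purrr::pmap(plants, function(sample, chrom, start, end,
                                                seen_by, manta_filter,
                                                manta_imprecise, canvas_qual,
                                                expected, reason) {
    f <- spec$breakpoint_jitter_fraction
    rows <- list()
    if (seen_by %in% c("both", "manta_only")) {
      iv <- if (seen_by == "both") jitter_interval(start, end, f) else c(start, end)
      rows$manta <- tibble(caller = "manta", sample_id = sample,
                           chrom = chrom, start = as.integer(iv[1]),
                           end = as.integer(iv[2]), filter = manta_filter,
                           qual = NA_real_, imprecise = manta_imprecise)
    }
    if (seen_by %in% c("both", "canvas_only")) {
      iv <- if (seen_by == "both") jitter_interval(start, end, f) else c(start, end)
      rows$canvas <- tibble(caller = "canvas", sample_id = sample,
                            chrom = chrom, start = as.integer(iv[1]),
                            end = as.integer(iv[2]), filter = "PASS",
                            qual = canvas_qual, imprecise = FALSE)
    }
    list_rbind(rows)
  }) |> list_rbind()

  calls <- dplyr::bind_rows(background, planted_calls) |>
    arrange(.data$caller, .data$sample_id, .data$chrom, .data$start) |>
    mutate(call_id = sprintf("%s_%s_%05d", .data$caller, .data$sample_id,
                             dplyr::row_number()))

  pathogenic <- tibble(chrom = "chr2", start = 20e6L, end = 21e6L,
                       label = "known_pathogenic_region_1")

  paths <- list(
    manta = file.path(dir, "manta_dels.tsv"),
    canvas = file.path(dir, "canvas_dels.tsv"),
    exclusion = file.path(dir, "cnv_exclusion.bed"),
    morbid_genes = file.path(dir, "morbid_genes.bed"),
    pathogenic = file.path(dir, "pathogenic_cnvs.bed"),
    pli = file.path(dir, "pli.tsv"),
    truth = file.path(dir, "truth_cnvs.tsv")
  )
  readr::write_tsv(calls |> filter(.data$caller == "manta"), paths$manta)
  readr::write_tsv(calls |> filter(.data$caller == "canvas"), paths$canvas)
  bed_out <- function(d, p) {
    readr::write_tsv(d |> select("chrom", "start", "end", "label"), p,
                     col_names = FALSE)
  }
  bed_out(exclusion, paths$exclusion)
  bed_out(morbid, paths$morbid_genes)
  bed_out(pathogenic, paths$pathogenic)
  readr::write_tsv(pli, paths$pli)
  truth <- plants |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("sample", "chrom", "start", "end", "seen_by", "expected", "reason")
  readr::write_tsv(truth, paths$truth)
  invisible(list(paths = paths, truth = truth))
}
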