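test_that("genotyping-rate filter uses a strict fraction threshold", {
  samples <- sprintf("P%02d", 1:28)
  v <- toy_variants(2)
  # v001: 15/28 genotyped (0.536 > 0.5) kept; v002: 14/28 (= 0.5) removed
  g <- dplyr::bind_rows(
    toy_genotypes(v[1, ], samples) |>
      dplyr::mutate(gt = ifelse(dplyr::row_number() <= 15, "het", "missing")),
    toy_genotypes(v[2, ], samples) |>
      dplyr::mutate(gt = ifelse(dplyr::row_number() <= 14, "het", "missing")))
  out <- filter_genotyped_fraction(v, g, samples, 0.5)
  expect_equal(out$variant_id, "v001")

  # 10/10 genotyped passes the 0.9 setting
  s10 <- sprintf("Q%02d", 1:10)
  g10 <- toy_genotypes(v[1, ], s10)
  expect_equal(nrow(filter_genotyped_fraction(v[1, ], g10, s10, 0.9)), 1)
})

test_that("repeat/segdup exclusion accepts either positional or flag evidence", {
  iv <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L, label = "rep")
  v <- toy_variants(3, pos = c(150L, 500L, 600L),
                    in_repeat_or_segdup = c(FALSE, TRUE, FALSE))
  out <- filter_repeat_segdup(v, iv)
  expect_equal(out$variant_id, "v003")
  # empty region set and false flags keep everything
  out2 <- filter_repeat_segdup(v |> dplyr::mutate(in_repeat_or_segdup = FALSE),
                               iv[0, ])
  expect_equal(nrow(out2), 3)
})

test_that("region filter matches a brute-force membership scan", {
  set.seed(7)
  iv <- tibble::tibble(chrom = "chr1", start = sort(sample.int(5000, 20)))
  iv$end <- iv$start + sample.int(200, 20)
  iv$label <- "rep"
  v <- toy_variants(100, pos = sample.int(6000, 100))
  out <- filter_repeat_segdup(v, iv)
  keep_bf <- !bf_point_in(v$chrom, v$pos, iv)
  expect_equal(out$variant_id, v$variant_id[keep_bf])
})

test_that("allele-frequency thresholds are strict and model-specific", {
  v <- toy_variants(3, af_gnomad_v2 = c(0.0005, NA, 0.001))
  rec <- filter_allele_frequency(v, "recessive")
  dom <- filter_allele_frequency(v, "dominant")
  expect_setequal(rec$variant_id, c("v001", "v002"))  # 0.001 exactly fails <
  expect_equal(dom$variant_id, "v002")                # absent = 0 passes
  expect_error(filter_allele_frequency(v, "additive"), "model")
  # dominant survivors are always a subset of recessive survivors
  expect_true(all(dom$variant_id %in% rec$variant_id))
})

test_that("AF-zero filter equals a per-record any() scan over databases", {
  set.seed(11)
  v <- toy_variants(50)
  dbs <- paste0("af_", c("gnomad_v2", "gnomad_v3", "kaviar", "krgdb",
                         "togovar", "inhouse"))
  for (db in dbs) {
    v[[db]] <- ifelse(runif(50) < 0.5, NA_real_,
                      sample(c(0, 1e-5, 1e-3), 50, replace = TRUE))
  }
  out <- filter_af_zero(v)
  m <- as.matrix(v[, dbs]); m[is.na(m)] <- 0
  expect_equal(out$variant_id, v$variant_id[rowSums(m > 0) == 0])
  # a single observation anywhere removes the record
  v1 <- toy_variants(1, af_togovar = 1e-5)
  expect_equal(nrow(filter_af_zero(v1)), 0)
})

test_that("gene-tier restriction is cumulative", {
  f <- tempfile()
  readr::write_tsv(tibble::tibble(gene = c("HDAC4", "KMT2E", "OMG1"),
                                  tier = c("E", "S", "O"),
                                  inheritance = c("AD", "AD", "")), f)
  catalog <- read_gene_sets(f)
  v <- toy_variants(4, gene = c("HDAC4", "KMT2E", "OMG1", NA))
  expect_equal(filter_gene_tier(v, catalog, "E")$gene, "HDAC4")
  expect_setequal(filter_gene_tier(v, catalog, "S")$gene, c("HDAC4", "KMT2E"))
  expect_setequal(filter_gene_tier(v, catalog, "O")$gene,
                  c("HDAC4", "KMT2E", "OMG1"))
  expect_equal(nrow(filter_gene_tier(v, catalog, "any")), 4)
})

test_that("non-silent selection includes predicted splice-altering variants", {
  v <- toy_variants(
    4,
    consequence = c("stopgain", "intronic", "intronic", "synonymous"),
    rf_score = c(NA, 0.2, NA, NA),
    ada_score = c(NA, 0.1, 0.7, NA))
  out <- select_nonsilent(v)
  expect_setequal(out$variant_id, c("v001", "v003"))
  # CADD-Splice flag alone is sufficient; score exactly 0.6 is not
  v2 <- toy_variants(2, consequence = "intronic",
                     ada_score = c(0.6, NA),
                     cadd_splice_flag = c(FALSE, TRUE))
  expect_equal(select_nonsilent(v2)$variant_id, "v002")
})

test_that("stepwise filters 2-4 commute on random batches", {
  set.seed(23)
  catf <- tempfile()
  readr::write_tsv(tibble::tibble(gene = c("G1", "G2"), tier = c("E", "S"),
                                  inheritance = c("AD", "AR")), catf)
  catalog <- read_gene_sets(catf)
  iv <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L),
                       end = c(1000L, 7000L), label = "rep")
  for (rep_i in 1:5) {
    v <- toy_variants(60, pos = sample.int(10000, 60),
                      gene = sample(c("G1", "G2", NA), 60, replace = TRUE),
                      af_gnomad_v2 = sample(c(NA, 0, 1e-6, 1e-4, 0.01), 60,
                                            replace = TRUE))
    a <- v |> filter_repeat_segdup(iv) |>
      filter_allele_frequency("recessive") |>
      filter_gene_tier(catalog, "S")
    b <- v |> filter_gene_tier(catalog, "S") |>
      filter_allele_frequency("recessive") |>
      filter_repeat_segdup(iv)
    expect_setequal(a$variant_id, b$variant_id)
  }
})

test_that("filter traces chain and are monotone", {
  set.seed(31)
  v <- toy_variants(40, af_gnomad_v2 = sample(c(NA, 1e-4, 0.01), 40,
                                              replace = TRUE))
  iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 2000L, label = "rep")
  out <- v |> filter_repeat_segdup(iv) |> filter_allele_frequency("recessive") |>
    filter_af_zero()
  tr <- filter_trace(out)
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$n_out <= tr$n_in))
  expect_equal(tr$n_in[-1], tr$n_out[-nrow(tr)])
  expect_equal(tr$n_out[nrow(tr)], nrow(out))
})

test_that("stringent depth/VAF thresholds sit exactly at the documented bounds", {
  samples <- sprintf("P%02d", 1:10)
  catf <- tempfile()
  readr::write_tsv(tibble::tibble(gene = "KMT2E", tier = "S",
                                  inheritance = "AD"), catf)
  catalog <- read_gene_sets(catf)
  v <- toy_variants(4, gene = "KMT2E")
  depth_cases <- list(
    v001 = c(36L, 35L),  # depth 71, VAF 0.493 -> survives
    v002 = c(12L, 3L),   # depth 15 but VAF 0.2 -> fails VAF
    v003 = c(10L, 4L),   # depth 14 -> fails depth regardless of VAF
    v004 = c(21L, 9L))   # depth 30, VAF exactly 0.3 -> survives
  g <- purrr::imap(depth_cases, function(ad, vid) {
    toy_genotypes(v[v$variant_id == vid, ], samples, gt = "hom_ref",
                  ref_depth = 30L, alt_depth = 0L) |>
      dplyr::mutate(gt = ifelse(sample_id == "P01", "het", gt),
                    ref_depth = ifelse(sample_id == "P01", ad[1], ref_depth),
                    alt_depth = ifelse(sample_id == "P01", ad[2], alt_depth))
  }) |> purrr::list_rbind()
  out <- apply_stringent_filters(v, g, "P01", "singleton_dominant", catalog)
  expect_setequal(out$variant_id, c("v001", "v004"))
  # depth 15 with VAF exactly 0.3 is accepted
  g2 <- toy_genotypes(v[1, ], samples, gt = "hom_ref", alt_depth = 0L) |>
    dplyr::mutate(gt = ifelse(sample_id == "P01", "het", gt),
                  ref_depth = ifelse(sample_id == "P01", 10L, ref_depth),
                  alt_depth = ifelse(sample_id == "P01", 5L, alt_depth))
  out2 <- apply_stringent_filters(v[1, ], g2, "P01", "singleton_dominant",
                                  catalog)
  expect_equal(out2$variant_id, "v001")
})

test_that("stringent modes apply the documented filter subsets", {
  samples <- sprintf("P%02d", 1:10)
  catf <- tempfile()
  readr::write_tsv(tibble::tibble(gene = c("ADG", "ARG"), tier = c("S", "S"),
                                  inheritance = c("AD", "AR")), catf)
  catalog <- read_gene_sets(catf)
  # one variant seen in a database (fails AF-zero), in an AR gene (fails
  # dominant-gene), genotyped everywhere with clean depths
  v <- toy_variants(2, gene = c("ARG", "ADG"),
                    af_kaviar = c(1e-4, NA))
  g <- toy_genotypes(v, samples, gt = "hom_ref", alt_depth = 0L) |>
    dplyr::mutate(gt = ifelse(sample_id == "P01", "het", gt),
                  alt_depth = ifelse(sample_id == "P01", 30L, alt_depth))
  # trio_recessive (filters 1-3): both survive
  expect_equal(nrow(apply_stringent_filters(v, g, "P01", "trio_recessive",
                                            catalog)), 2)
  # trio_denovo adds AF-zero: the kaviar-seen record drops
  expect_equal(apply_stringent_filters(v, g, "P01", "trio_denovo",
                                       catalog)$variant_id, "v002")
  # singleton_dominant adds the dominant-gene model requirement
  out <- apply_stringent_filters(v, g, "P01", "singleton_dominant", catalog)
  expect_equal(out$gene, "ADG")
  expect_error(apply_stringent_filters(v, g, "P01", "other", catalog), "mode")
})

test_that("biallelic-site filter keeps only single-ALT original sites", {
  samples <- sprintf("P%02d", 1:10)
  v <- toy_variants(2, n_alt_site = c(1L, 2L))
  g <- toy_genotypes(v, samples, gt = "hom_ref", alt_depth = 0L) |>
    dplyr::mutate(gt = ifelse(sample_id == "P01", "het", gt),
                  alt_depth = ifelse(sample_id == "P01", 30L, alt_depth))
  out <- apply_stringent_filters(v, g, "P01", "trio_recessive")
  expect_equal(out$variant_id, "v001")
})
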