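mk_trio <- function(child, father, mother,
                    fa_ad = 0L, mo_ad = 0L, fa_dp = 50L, mo_dp = 50L,
                    variant_id = "v1") {
  tibble::tibble(
    variant_id = variant_id,
    gt_child = child, gt_father = father, gt_mother = mother,
    ref_depth_child = 30L, alt_depth_child = 30L,
    ref_depth_father = fa_dp - fa_ad, alt_depth_father = fa_ad,
    ref_depth_mother = mo_dp - mo_ad, alt_depth_mother = mo_ad)
}

test_that("de novo calls require clean, well-covered reference parents", {
  # child het, parents hom-ref with zero alt reads at depth >= 15
  expect_true(call_de_novo(mk_trio("het", "hom_ref", "hom_ref")))
  # inherited: father het
  expect_false(call_de_novo(mk_trio("het", "het", "hom_ref", fa_ad = 20L)))
  # parental evidence: two stray alt reads in the mother veto the call
  expect_false(call_de_novo(mk_trio("het", "hom_ref", "hom_ref", mo_ad = 2L)))
  # shallow parent (depth 10) vetoes the call
  expect_false(call_de_novo(mk_trio("het", "hom_ref", "hom_ref", mo_dp = 10L)))
  # male chrX: hemi_alt child with hemi_ref father is callable
  expect_true(call_de_novo(mk_trio("hemi_alt", "hemi_ref", "hom_ref")))
  # missing parent genotype is never de novo
  expect_false(call_de_novo(mk_trio("het", "missing", "hom_ref")))
})

test_that("de novo agrees with exhaustive genotype-combination enumeration", {
  states <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(child = c("het", "hom_ref", "hom_alt"),
                      father = states, mother = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    fa_ad <- if (grid$father[i] %in% c("het", "hom_alt")) 25L else 0L
    mo_ad <- if (grid$mother[i] %in% c("het", "hom_alt")) 25L else 0L
    got <- call_de_novo(mk_trio(grid$child[i], grid$father[i], grid$mother[i],
                                fa_ad = fa_ad, mo_ad = mo_ad))
    # independent statement of the rule
    want <- grid$child[i] == "het" &&
      grid$father[i] == "hom_ref" && grid$mother[i] == "hom_ref"
    expect_identical(got, want,
                     info = paste(grid[i, ], collapse = "/"))
  }
})

test_that("single-record trio states partition every genotype combination", {
  states <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(child = states, father = states, mother = states,
                      stringsAsFactors = FALSE)
  tr <- purrr::pmap(grid, function(child, father, mother) {
    mk_trio(child, father, mother,
            fa_ad = if (father %in% c("het", "hom_alt")) 25L else 0L,
            mo_ad = if (mother %in% c("het", "hom_alt")) 25L else 0L)
  }) |> purrr::list_rbind()
  states_out <- trioscreen:::classify_trio_record(tr)
  expect_true(all(states_out %in% c("de_novo_het", "hom_recessive",
                                    "hemizygous", "inherited", "uncalled",
                                    "not_carried")))
  # each combination yields exactly one state (vector output, no NAs)
  expect_equal(length(states_out), nrow(grid))
  expect_false(anyNA(states_out))
})

test_that("compound-het pairing demands in-trans transmission", {
  # one paternal, one maternal record -> exactly one pair (both orders)
  tr <- dplyr::bind_rows(
    mk_trio("het", "het", "hom_ref", fa_ad = 25L, variant_id = "a"),
    mk_trio("het", "hom_ref", "het", mo_ad = 25L, variant_id = "b"))
  calls <- call_recessive(tr)
  expect_equal(sum(calls$pattern == "compound_het"), 2)
  expect_equal(dplyr::n_distinct(calls$pair_id), 1)
  expect_setequal(calls$parent_of_origin, c("father", "mother"))

  # swapping which parent carries which variant still yields one pair
  tr_swap <- dplyr::bind_rows(
    mk_trio("het", "hom_ref", "het", mo_ad = 25L, variant_id = "a"),
    mk_trio("het", "het", "hom_ref", fa_ad = 25L, variant_id = "b"))
  expect_equal(dplyr::n_distinct(call_recessive(tr_swap)$pair_id), 1)

  # two variants both from the father are in cis: no pair
  tr_cis <- dplyr::bind_rows(
    mk_trio("het", "het", "hom_ref", fa_ad = 25L, variant_id = "a"),
    mk_trio("het", "het", "hom_ref", fa_ad = 25L, variant_id = "b"))
  expect_equal(nrow(call_recessive(tr_cis)), 0)

  # a record with both parents het is phase-ambiguous and anchors nothing
  tr_amb <- dplyr::bind_rows(
    mk_trio("het", "het", "het", fa_ad = 25L, mo_ad = 25L, variant_id = "a"),
    mk_trio("het", "hom_ref", "het", mo_ad = 25L, variant_id = "b"))
  expect_equal(nrow(call_recessive(tr_amb)), 0)
})

test_that("homozygous-recessive and hemizygous states are recognized", {
  hom <- mk_trio("hom_alt", "het", "het", fa_ad = 25L, mo_ad = 25L)
  calls <- call_recessive(hom)
  expect_equal(calls$pattern, "hom_recessive")

  hemi <- mk_trio("hemi_alt", "hemi_ref", "het", mo_ad = 25L)
  calls2 <- call_recessive(hemi)
  expect_equal(calls2$pattern, "hemizygous")
  expect_equal(calls2$parent_of_origin, "mother")
})

test_that("trio screening of the worked-example cohort recovers each class", {
  p <- example_paths()
  co <- read_cohort(p$vcf, p$ped)
  catalog <- read_gene_sets(p$gene_sets)
  ann <- read_annotations(p$annotations)
  v <- annotate_variants(co$variants, ann)
  cand <- screen_trio(v, co$genotypes, co$pedigree, catalog)
  # a compound-het pair contributes two rows: 5 rows for 4 findings
  expect_equal(nrow(cand), 5)
  by_gene <- setNames(cand$inheritance_pattern, cand$gene)
  expect_equal(by_gene[["HDAC4"]], "de_novo_het")
  expect_equal(by_gene[["SOX5"]], "de_novo_het")
  expect_equal(unname(by_gene[names(by_gene) == "GRM7"]),
               c("compound_het", "compound_het"))
  expect_equal(by_gene[["SHROOM4"]], "hemizygous")
  expect_equal(cand$model[cand$gene == "SHROOM4"], "XLR")
  # proband depths match the published allele counts
  expect_equal(cand$alt_depth[cand$gene == "SHROOM4"], 38L)
  expect_equal(cand$ref_depth[cand$gene == "HDAC4"], 28L)
})

test_that("singleton screening of the worked-example cohort finds both hits", {
  p <- example_paths()
  co <- read_cohort(p$vcf, p$ped)
  catalog <- read_gene_sets(p$gene_sets)
  v <- annotate_variants(co$variants, read_annotations(p$annotations))
  cand <- screen_singletons(v, co$genotypes, co$pedigree, catalog)
  expect_setequal(cand$gene, c("CACNA1E", "KMT2E"))
  expect_setequal(cand$sample_id, c("IS11", "IS15"))
  expect_equal(unique(cand$inheritance_pattern), "het_dominant")
  expect_setequal(cand$classification, c("LP", "P"))
})

test_that("screening an all-reference cohort yields no candidates", {
  p <- example_paths()
  co <- read_cohort(p$vcf, p$ped)
  catalog <- read_gene_sets(p$gene_sets)
  v <- annotate_variants(co$variants, read_annotations(p$annotations))
  # make every database report the variants as common
  v$af_gnomad_v2 <- 0.05
  cand_t <- screen_trio(v, co$genotypes, co$pedigree, catalog)
  cand_s <- screen_singletons(v, co$genotypes, co$pedigree, catalog)
  # trio recessive path has no AF gate, so compound het and hemizygous
  # survive; the de novo (AF-zero gated) and singleton calls vanish
  expect_false(any(cand_t$inheritance_pattern == "de_novo_het"))
  expect_equal(nrow(cand_s), 0)
})
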