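test_that("reciprocal overlap is symmetric with the documented values", {
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr1", 100, 200), 1)
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr1", 150, 250), 0.5)
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr1", 300, 400), 0)
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr2", 100, 200), 0)
  expect_equal(reciprocal_overlap("chr1", 1000, 2000, "chr1", 1100, 2100), 0.9)
  expect_equal(reciprocal_overlap("chr1", 1000, 2000, "chr1", 1650, 2650), 0.35)
  # symmetry on random pairs; 1 only for identical intervals
  set.seed(5)
  for (i in 1:50) {
    a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    f1 <- reciprocal_overlap("chr1", a[1], a[2], "chr1", b[1], b[2])
    f2 <- reciprocal_overlap("chr1", b[1], b[2], "chr1", a[1], a[2])
    expect_equal(f1, f2)
    expect_equal(f1 == 1, all(a == b))
  }
})

mk_call <- function(caller, start, end, sample_id = "S1", filter = "PASS",
                    qual = 30, imprecise = FALSE, id = NULL) {
  tibble::tibble(caller = caller, sample_id = sample_id, chrom = "chr1",
                 start = as.integer(start), end = as.integer(end),
                 filter = filter, qual = qual, imprecise = imprecise,
                 call_id = id %||% sprintf("%s_%d", caller, start))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("common-call matching is one-to-one with best overlap winning", {
  calls <- dplyr::bind_rows(
    mk_call("manta", 1000, 2000),
    mk_call("manta", 1120, 2120),
    mk_call("canvas", 1100, 2100))
  m <- match_common(calls)
  expect_equal(nrow(m$common), 1)
  # the closer manta call (overlap 0.98) wins; the other goes unmatched
  expect_equal(m$common$manta_id, "manta_1120")
  expect_equal(m$unmatched$call_id, "manta_1000")
  # overlap below the gate never matches
  far <- dplyr::bind_rows(mk_call("manta", 1000, 2000),
                          mk_call("canvas", 1650, 2650))
  expect_equal(nrow(match_common(far)$common), 0)
  # consensus coordinates are the intersection
  expect_equal(m$common$start, 1120L)
  expect_equal(m$common$end, 2100L)
})

test_that("matching never pairs calls across samples", {
  calls <- dplyr::bind_rows(
    mk_call("manta", 1000, 2000, sample_id = "S1"),
    mk_call("canvas", 1000, 2000, sample_id = "S2"))
  expect_equal(nrow(match_common(calls)$common), 0)
})

test_that("greedy matching equals brute-force maximum matching on small instances", {
  set.seed(99)
  for (i in 1:60) {
    manta <- random_disjoint_calls(sample(1:10, 1), "manta")
    shared <- manta[sample.int(nrow(manta), min(nrow(manta),
                                                sample(0:5, 1))), ]
    canvas <- dplyr::bind_rows(
      if (nrow(shared) > 0) jittered_copy(shared, "canvas", f = 0.1),
      random_disjoint_calls(sample(1:5, 1), "canvas2"))
    canvas$caller <- "canvas"
    canvas$call_id <- sprintf("canvas_%03d", seq_len(nrow(canvas)))
    m <- match_common(dplyr::bind_rows(manta, canvas))
    expect_equal(nrow(m$common), bf_max_matching(manta, canvas))
  }
})

test_that("equal-overlap ties break deterministically by combined length", {
  # two identical-overlap candidates; the smaller pair is chosen first
  calls <- dplyr::bind_rows(
    mk_call("manta", 1000, 2000, id = "m_small"),
    mk_call("manta", 10000, 12000, id = "m_big"),
    mk_call("canvas", 1000, 2000, id = "c_small"),
    mk_call("canvas", 10000, 12000, id = "c_big"))
  m <- match_common(calls)
  expect_equal(nrow(m$common), 2)
  expect_equal(m$common$manta_id[1], "m_small")
})

test_that("common gates remove long deletions and excluded regions", {
  excl <- tibble::tibble(chrom = "chr1", start = 5000L, end = 6000L,
                         label = "hla")
  cons <- tibble::tibble(
    sample_id = "S1", chrom = "chr1",
    start = c(0L, 5500L, 10000L),
    end = c(60000000L, 5600L, 510000L),
    support = "both")
  out <- filter_common(cons, excl, consensus_config(max_common_length = 50e6))
  expect_equal(out$start, 10000L)  # 60 Mb and HLA-overlapping removed
  # exactly 50 Mb is rejected (strict <)
  cons50 <- tibble::tibble(sample_id = "S1", chrom = "chr1", start = 0L,
                           end = 50000000L, support = "both")
  expect_equal(nrow(filter_common(cons50, excl[0, ])), 0)
})

test_that("manta-only rescue requires PASS, precise, and <1 Mb", {
  calls <- dplyr::bind_rows(
    mk_call("manta", 0, 800000, id = "ok"),
    mk_call("manta", 0, 1200000, id = "too_long"),
    mk_call("manta", 0, 500000, imprecise = TRUE, id = "imprecise"),
    mk_call("manta", 0, 500000, filter = "MinGQ", id = "not_pass"),
    mk_call("manta", 0, 1000000, id = "exactly_1mb"))
  out <- filter_manta_only(calls)
  expect_equal(out$call_id, "ok")
})

test_that("canvas-only rescue enforces QUAL and over-called sample removal", {
  calls <- dplyr::bind_rows(
    mk_call("canvas", 0, 1000, qual = 9, id = "lowq"),
    mk_call("canvas", 0, 1000, qual = 10, id = "boundary"),
    mk_call("canvas", 0, 1000, qual = 25, id = "overcalled",
            sample_id = "BAD"),
    mk_call("canvas", 0, 1000, qual = 25, id = "good"))
  out <- filter_canvas_only(calls, overcalled_samples = "BAD")
  expect_setequal(out$call_id, c("boundary", "good"))  # QUAL 10 accepted
})

test_that("over-called sample detection uses the median of the other samples", {
  counts <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                           n = c(100, 110, 120, 400))
  expect_equal(detect_overcalled_samples(counts, 3), "D")  # 400 > 3 x 110
  same <- tibble::tibble(sample_id = c("A", "B", "C"), n = c(50, 50, 50))
  expect_equal(detect_overcalled_samples(same, 3), character(0))
  # boundary: exactly 3 x median is not flagged (strict >)
  edge <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         n = c(100, 100, 100, 300))
  expect_equal(detect_overcalled_samples(edge, 3), character(0))
})

test_that("annotation flags reportable deletions by pLI or pathogenic region", {
  morbid <- tibble::tibble(chrom = "chr1", start = c(1000L, 9000L),
                           end = c(2000L, 9500L), label = c("GENEHI", "GENELO"))
  patho <- tibble::tibble(chrom = "chr1", start = 50000L, end = 60000L,
                          label = "patho1")
  pli <- tibble::tibble(gene = c("GENEHI", "GENELO"), pli = c(1.0, 0.0))
  cons <- tibble::tibble(
    sample_id = "S1", chrom = "chr1",
    start = c(900L, 8900L, 55000L, 70000L),
    end = c(2100L, 9600L, 56000L, 71000L),
    support = "both")
  out <- annotate_cnv(cons, morbid, patho, pli)
  expect_equal(out$reportable, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$gene_hits[[1]], "GENEHI")
  expect_equal(out$max_pli[2], 0)
  expect_equal(out$pathogenic_region_hits[[3]], "patho1")
})

test_that("full consensus on the default synthetic call sets honors the truth table", {
  cv <- default_cnv_bundle()
  calls <- dplyr::bind_rows(read_cnv_tsv(cv$paths$manta),
                            read_cnv_tsv(cv$paths$canvas))
  excl <- read_regions(cv$paths$exclusion, "exclusion")
  morbid <- read_regions(cv$paths$morbid_genes, merge = FALSE)
  patho <- read_regions(cv$paths$pathogenic, merge = FALSE)
  pli <- readr::read_tsv(cv$paths$pli, show_col_types = FALSE)
  res <- cnv_consensus(calls, excl, morbid, patho, pli)
  expect_equal(res$overcalled_samples, "IS16")
  dels <- res$deletions
  for (i in seq_len(nrow(cv$truth))) {
    tr <- cv$truth[i, ]
    hit <- dels[dels$sample_id == tr$sample & dels$chrom == tr$chrom, ]
    ro <- if (nrow(hit) == 0) numeric(0) else
      reciprocal_overlap(hit$chrom, hit$start, hit$end,
                         tr$chrom, tr$start, tr$end)
    matched <- hit[ro >= 0.5, ]
    if (tr$expected == "removed") {
      expect_equal(nrow(matched), 0, info = tr$reason)
    } else {
      expect_equal(nrow(matched), 1, info = tr$reason)
      expect_equal(matched$support, sub("kept_", "", tr$expected),
                   info = tr$reason)
    }
  }
  # the true dual-caller deletion over the pLI-1.0 morbid gene is reportable
  both <- dels[dels$sample_id == "IS03" & dels$support == "both", ]
  expect_true(any(both$reportable))
})
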