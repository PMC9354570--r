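# Dual-caller deletion consensus: reciprocal-overlap matching of Manta- and
# Canvas-style call sets within each sample, exclusion/size gates on common
# calls, caller-specific rescue filters for unmatched calls, over-called
# sample detection, and morbid-gene / pathogenic-region annotation.

#' Consensus thresholds for dual-caller deletion merging
#'
#' @param min_overlap_fraction Reciprocal-overlap fraction for a common call
#'   (`>=`; default 0.70).
#' @param max_common_length Maximum deletion length, in bp (strict `<`;
#'   default 50 Mb).
#' @param manta_only_max_length Length ceiling for Manta-only rescues
#'   (strict `<`; default 1 Mb).
#' @param canvas_min_qual Minimum QUAL for Canvas-only rescues (`>=`;
#'   default 10).
#' @param overcall_factor A sample is over-called when its deletion count
#'   exceeds this multiple of the median count of the other samples
#'   (strict `>`; default 3).
#' @param reciprocal Use reciprocal overlap (min of the two mutual
#'   fractions); `FALSE` switches to one-way overlap (max).
#' @param consensus_coords `"intersection"` (default) or `"union"` interval
#'   for a matched pair.
#' @param min_pli pLI threshold above which a morbid-gene hit makes a
#'   deletion reportable (`>=`; default 0.9).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_overlap_fraction = 0.70,
                             max_common_length = 50e6,
                             manta_only_max_length = 1e6,
                             canvas_min_qual = 10,
                             overcall_factor = 3.0,
                             reciprocal = TRUE,
                             consensus_coords = c("intersection", "union"),
                             min_pli = 0.9) {
  stopifnot(min_overlap_fraction > 0, min_overlap_fraction <= 1,
            max_common_length > 0, manta_only_max_length > 0)
  consensus_coords <- match.arg(consensus_coords)
  structure(as.list(environment()), class = "consensus_config")
}

#' Reciprocal overlap fraction of two genomic intervals
#'
#' `min(olen / len(a), olen / len(b))` where `olen` is the intersection
#' length; 0 for different chromosomes, 1 iff the intervals are identical.
#' Vectorized over rows.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Interval coordinates,
#'   0-based half-open.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b) {
  olen <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  frac <- pmin(olen / (end_a - start_a), olen / (end_b - start_b))
  ifelse(chrom_a == chrom_b, frac, 0)
}

one_way_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  olen <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  frac <- pmax(olen / (end_a - start_a), olen / (end_b - start_b))
  ifelse(chrom_a == chrom_b, frac, 0)
}

#' Match deletion calls from two callers into common consensus calls
#'
#' Within each sample, candidate pairs with overlap at or above the
#' threshold are matched greedily in order of descending overlap fraction
#' (ties: smaller combined length, then coordinate order); each call is used
#' at most once. Matched pairs become `support = "both"` consensus deletions
#' with intersection (or union) coordinates; unmatched calls are returned
#' for caller-specific rescue filtering.
#'
#' @param calls Combined call table ([read_cnv_tsv()] /
#'   [read_sv_vcf()] rows from both callers).
#' @param config A [consensus_config()].
#' @return A list with `common` (consensus tibble: `sample_id`, `chrom`,
#'   `start`, `end`, `support`, `manta_id`, `canvas_id`, `overlap`) and
#'   `unmatched` (leftover calls).
#' @export
match_common <- function(calls, config = consensus_config()) {
  ofun <- if (config$reciprocal) reciprocal_overlap else one_way_overlap
  common <- list()
  matched_ids <- character()
  for (s in unique(calls$sample_id)) {
    manta <- calls |> filter(.data$sample_id == s, .data$caller == "manta")
    canvas <- calls |> filter(.data$sample_id == s, .data$caller == "canvas")
    if (nrow(manta) == 0 || nrow(canvas) == 0) next
    pairs <- tidyr::expand_grid(i = seq_len(nrow(manta)),
                                j = seq_len(nrow(canvas)))
    pairs$overlap <- ofun(manta$chrom[pairs$i], manta$start[pairs$i],
                          manta$end[pairs$i], canvas$chrom[pairs$j],
                          canvas$start[pairs$j], canvas$end[pairs$j])
    pairs <- pairs |>
      filter(.data$overlap >= config$min_overlap_fraction) |>
      mutate(comb_len = (manta$end[.data$i] - manta$start[.data$i]) +
               (canvas$end[.data$j] - canvas$start[.data$j])) |>
      arrange(dplyr::desc(.data$overlap), .data$comb_len,
              manta$chrom[.data$i], manta$start[.data$i],
              canvas$start[.data$j])
    used_i <- integer(); used_j <- integer()
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (i %in% used_i || j %in% used_j) next
      used_i <- c(used_i, i); used_j <- c(used_j, j)
      if (config$consensus_coords == "intersection") {
        st <- max(manta$start[i], canvas$start[j])
        en <- min(manta$end[i], canvas$end[j])
      } else {
        st <- min(manta$start[i], canvas$start[j])
        en <- max(manta$end[i], canvas$end[j])
      }
      common[[length(common) + 1]] <- tibble(
        sample_id = s, chrom = manta$chrom[i], start = st, end = en,
        support = "both", manta_id = manta$call_id[i],
        canvas_id = canvas$call_id[j], overlap = pairs$overlap[k])
      matched_ids <- c(matched_ids, manta$call_id[i], canvas$call_id[j])
    }
  }
  common <- if (length(common) > 0) list_rbind(common) else
    tibble(sample_id = character(), chrom = character(), start = integer(),
           end = integer(), support = character(), manta_id = character(),
           canvas_id = character(), overlap = numeric())
  list(common = common,
       unmatched = calls |> filter(!.data$call_id %in% matched_ids))
}

#' Apply the common-deletion gates: exclusion regions and size
#'
#' Removes consensus deletions overlapping any exclusion interval by at
#' least one base pair, or with length at or above the ceiling.
#'
#' @param consensus Consensus deletion table.
#' @param exclusion_index Interval table of exclusion regions (low
#'   mappability, centromeres/telomeres, segmental duplications, IG/HLA
#'   loci).
#' @param config A [consensus_config()].
#' @return The kept subset.
#' @export
filter_common <- function(consensus, exclusion_index,
                          config = consensus_config()) {
  if (nrow(consensus) == 0) return(consensus)
  len_ok <- (consensus$end - consensus$start) < config$max_common_length
  excl <- intervals_overlap_any(consensus, exclusion_index)
  consensus[len_ok & !excl, , drop = FALSE]
}

#' Rescue filter for Manta-only deletion calls
#'
#' Keeps unmatched Manta calls with `FILTER == "PASS"`, length below 1 Mb,
#' and no IMPRECISE flag, then applies the common exclusion/size gates.
#'
#' @param calls Unmatched Manta call table.
#' @param exclusion_index Exclusion interval table.
#' @param config A [consensus_config()].
#' @return The kept calls as consensus rows (`support = "manta_only"`).
#' @export
filter_manta_only <- function(calls, exclusion_index = NULL,
                              config = consensus_config()) {
  keep <- calls$filter == "PASS" &
    (calls$end - calls$start) < config$manta_only_max_length &
    !calls$imprecise
  out <- calls[keep & !is.na(keep), , drop = FALSE] |>
    mutate(support = "manta_only")
  if (!is.null(exclusion_index)) {
    out <- filter_common(out, exclusion_index, config)
  }
  out
}

#' Detect over-called samples from per-sample deletion counts
#'
#' A sample is flagged when its count strictly exceeds `factor` times the
#' median count of all other samples. Evaluated once per sample against the
#' original counts (no re-computation after removals).
#'
#' @param counts A tibble with columns `sample_id` and `n`.
#' @param factor Over-call multiple (default 3).
#' @return Character vector of flagged sample ids.
#' @export
detect_overcalled_samples <- function(counts, factor = 3.0) {
  stopifnot(nrow(counts) >= 3, all(counts$n >= 0))
  flagged <- map_lgl(seq_len(nrow(counts)), function(i) {
    counts$n[i] > factor * median(counts$n[-i])
  })
  counts$sample_id[flagged]
}

#' Rescue filter for Canvas-only deletion calls
#'
#' Keeps unmatched Canvas calls with `QUAL >= 10` from samples not flagged
#' as over-called, then applies the common exclusion/size gates.
#'
#' @param calls Unmatched Canvas call table.
#' @param overcalled_samples Sample ids flagged by
#'   [detect_overcalled_samples()].
#' @param exclusion_index Exclusion interval table.
#' @param config A [consensus_config()].
#' @return The kept calls as consensus rows (`support = "canvas_only"`).
#' @export
filter_canvas_only <- function(calls, overcalled_samples = character(),
                               exclusion_index = NULL,
                               config = consensus_config()) {
  keep <- !is.na(calls$qual) & calls$qual >= config$canvas_min_qual &
    !calls$sample_id %in% overcalled_samples
  out <- calls[keep, , drop = FALSE] |> mutate(support = "canvas_only")
  if (!is.null(exclusion_index)) {
    out <- filter_common(out, exclusion_index, config)
  }
  out
}

#' Annotate consensus deletions with gene and pathogenic-region overlaps
#'
#' Records overlapping morbid genes (with their pLI scores) and overlapping
#' known-pathogenic CNV regions. A deletion is `reportable` when it hits a
#' morbid gene whose pLI meets the threshold, or any pathogenic region.
#'
#' @param consensus Consensus deletion table.
#' @param morbid_genes Interval table with gene symbols as labels
#'   ([read_regions()] with `merge = FALSE`).
#' @param pathogenic_regions Interval table of known-pathogenic CNVs.
#' @param pli Two-column table `gene`, `pli`.
#' @param config A [consensus_config()].
#' @return `consensus` with list-column `gene_hits`, `max_pli`,
#'   list-column `pathogenic_region_hits`, and logical `reportable`.
#' @export
annotate_cnv <- function(consensus, morbid_genes, pathogenic_regions,
                         pli = NULL, config = consensus_config()) {
  gene_hits <- interval_hits(consensus, morbid_genes)
  region_hits <- interval_hits(consensus, pathogenic_regions)
  pli_lookup <- function(genes) {
    if (is.null(pli) || length(genes) == 0) return(NA_real_)
    v <- pli$pli[match(genes, pli$gene)]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  max_pli <- map_dbl(gene_hits, pli_lookup)
  consensus |>
    mutate(gene_hits = gene_hits,
           max_pli = max_pli,
           pathogenic_region_hits = region_hits,
           reportable = lengths(region_hits) > 0 |
             (lengths(gene_hits) > 0 &
                dplyr::coalesce(max_pli >= config$min_pli, FALSE)))
}

#' Run the full dual-caller deletion consensus pipeline
#'
#' Matches common calls, applies the common gates, rescues caller-specific
#' calls through their filters (including over-called-sample removal for
#' Canvas), and annotates the surviving deletions.
#'
#' @param calls Combined deletion call table from both callers.
#' @param exclusion_index Exclusion interval table.
#' @param morbid_genes,pathogenic_regions,pli Optional annotation inputs
#'   (see [annotate_cnv()]).
#' @param config A [consensus_config()].
#' @return A list of class `cnv_consensus`: `deletions` (filtered, annotated
#'   consensus table), `overcalled_samples`, `counts` (per-sample,
#'   per-caller raw call counts).
#' @export
cnv_consensus <- function(calls, exclusion_index,
                          morbid_genes = NULL, pathogenic_regions = NULL,
                          pli = NULL, config = consensus_config()) {
  counts <- calls |> count(.data$sample_id, .data$caller)
  matched <- match_common(calls, config)
  common <- filter_common(matched$common, exclusion_index, config)

  manta_rest <- matched$unmatched |> filter(.data$caller == "manta")
  canvas_rest <- matched$unmatched |> filter(.data$caller == "canvas")
  manta_keep <- filter_manta_only(manta_rest, exclusion_index, config)

  canvas_counts <- calls |>
    filter(.data$caller == "canvas") |>
    count(.data$sample_id, name = "n")
  overcalled <- if (nrow(canvas_counts) >= 3) {
    detect_overcalled_samples(canvas_counts, config$overcall_factor)
  } else character()
  canvas_keep <- filter_canvas_only(canvas_rest, overcalled,
                                    exclusion_index, config)

  cols <- c("sample_id", "chrom", "start", "end", "support")
  deletions <- dplyr::bind_rows(
    common |> select(dplyr::all_of(c(cols, "manta_id", "canvas_id", "overlap"))),
    manta_keep |> mutate(manta_id = .data$call_id) |>
      select(dplyr::all_of(cols), "manta_id"),
    canvas_keep |> mutate(canvas_id = .data$call_id) |>
      select(dplyr::all_of(cols), "canvas_id")
  ) |> arrange(.data$sample_id, .data$chrom, .data$start)
  if (!is.null(morbid_genes)) {
    deletions <- annotate_cnv(deletions, morbid_genes,
                              pathogenic_regions %||%
                                morbid_genes[0, , drop = FALSE],
                              pli, config)
  }
  structure(list(deletions = deletions, overcalled_samples = overcalled,
                 counts = counts),
            class = "cnv_consensus")
}

#' @export
print.cnv_consensus <- function(x, ...) {
  cat(sprintf("<cnv_consensus> %d deletions (%d both, %d manta-only, %d canvas-only); %d over-called sample(s)\n",
              nrow(x$deletions), sum(x$deletions$support == "both"),
              sum(x$deletions$support == "manta_only"),
              sum(x$deletions$support == "canvas_only"),
              length(x$overcalled_samples)))
  invisible(x)
}
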