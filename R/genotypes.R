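# Genotype state vocabulary. VCF GT strings are normalized to one of:
#   hom_ref, het, hom_alt   -- diploid calls
#   hemi_ref, hemi_alt      -- single-copy calls (male chrX outside any PAR)
#   missing                 -- ./. or .
GT_STATES <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")
GT_CARRIER <- c("het", "hom_alt", "hemi_alt")

# Normalize a GT string (for the allele index `alt_idx` of a decomposed
# multi-allelic site) to a genotype state. `hemi` marks calls to be read as
# single-copy. Alleles other than 0 or alt_idx count as ref after
# decomposition (the other ALT is carried by its own record).
normalize_gt <- function(gt, alt_idx = 1L, hemi = FALSE) {
  gt <- ifelse(is.na(gt), ".", gt)
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  alt_chr <- as.character(rep_len(alt_idx, length(alleles)))
  n_alt <- map_dbl(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) == 0 || any(a == ".")) return(NA_real_)
    sum(a == alt_chr[i])
  })
  n_all <- lengths(alleles)
  hemi <- rep_len(hemi, length(alleles))
  out <- dplyr::case_when(
    is.na(n_alt) ~ "missing",
    hemi & n_alt > 0 ~ "hemi_alt",
    hemi ~ "hemi_ref",
    n_all == 1 & n_alt > 0 ~ "hemi_alt",
    n_all == 1 ~ "hemi_ref",
    n_alt == 0 ~ "hom_ref",
    n_alt == n_all ~ "hom_alt",
    .default = "het"
  )
  out
}

#' Variant allele fraction of a genotype call
#'
#' `alt_depth / (ref_depth + alt_depth)`; `NA` when total depth is zero.
#' The same formula applies to hemizygous calls.
#'
#' @param ref_depth,alt_depth Read counts supporting the reference and
#'   alternate allele.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gt_vaf <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

# Parse AD strings ("28,32" for a biallelic site) into ref/alt depths for
# allele `alt_idx`. Missing AD (".") with a present DP is treated as
# ref_depth = DP, alt_depth = 0 for hom_ref calls only; otherwise both
# depths are NA so the record fails any depth/VAF criterion (conservative).
parse_ad <- function(ad, alt_idx = 1L, gt_state = NULL, dp = NULL) {
  ad <- ifelse(is.na(ad), ".", ad)
  parts <- strsplit(ad, ",", fixed = TRUE)
  alt_idx <- rep_len(as.integer(alt_idx), length(parts))
  ref_d <- suppressWarnings(as.integer(map_chr(parts, 1)))
  alt_d <- suppressWarnings(as.integer(map_chr(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) >= alt_idx[i] + 1L) p[[alt_idx[i] + 1L]] else NA_character_
  })))
  if (!is.null(dp) && !is.null(gt_state)) {
    fill <- is.na(ref_d) & !is.na(dp) & gt_state %in% c("hom_ref", "hemi_ref")
    ref_d[fill] <- as.integer(dp[fill])
    alt_d[fill] <- 0L
  }
  list(ref_depth = ref_d, alt_depth = alt_d)
}
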