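# Genomic intervals are carried as tibbles with columns chrom, start, end
# (0-based, half-open -- the BED convention) plus an optional label column.
# IRanges is 1-based closed; every conversion between the two conventions
# goes through vcf_pos_to_bed()/bed_to_iranges() and nowhere else.

#' Convert a 1-based VCF position to a 0-based half-open point interval
#'
#' The single point of coordinate-convention truth in the package: VCF
#' positions are 1-based, interval structures 0-based half-open, so VCF
#' position `p` occupies `[p - 1, p)`.
#'
#' @param pos Integer vector of 1-based positions.
#' @return A tibble with columns `start` (`pos - 1`) and `end` (`pos`).
#' @export
#' @examples
#' vcf_pos_to_bed(150L) # start 149, end 150
vcf_pos_to_bed <- function(pos) {
  stopifnot(all(pos >= 1))
  tibble(start = as.integer(pos) - 1L, end = as.integer(pos))
}

# 0-based half-open [start, end) -> IRanges 1-based closed [start + 1, end]
bed_to_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

#' Read a BED file of genomic regions into a merged interval table
#'
#' Reads a BED3+ file (0-based half-open), merges overlapping or bookended
#' intervals per chromosome, and attaches a label. Used for repeat /
#' segmental-duplication masks, CNV exclusion regions, and morbid-gene or
#' pathogenic-CNV region sets.
#'
#' @param path Path to a BED file (3 or more tab-separated columns, no header).
#' @param label Label recorded on every interval (e.g. `"repeat"`).
#' @param merge Merge overlapping input intervals (default `TRUE`). With
#'   `merge = FALSE` a 4th BED column, when present, is kept as the per-line
#'   label (used for gene or region names).
#' @return A tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions <- function(path, label = "region", merge = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d has fewer than 3 columns", bad[1]))
  }
  out <- tibble(
    chrom = map_chr(fields, 1),
    start = as.integer(map_chr(fields, 2)),
    end   = as.integer(map_chr(fields, 3)),
    label = if (!merge && all(lengths(fields) >= 4)) map_chr(fields, 4) else label
  )
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: start >= end (%d >= %d)",
                  bad[1], out$start[bad[1]], out$end[bad[1]]))
  }
  out$chrom <- norm_chrom(out$chrom)
  if (merge) out <- merge_intervals(out)
  out
}

# Merge overlapping intervals per chromosome via IRanges::reduce.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  lab <- intervals$label[1]
  intervals |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      red <- IRanges::reduce(bed_to_iranges(d))
      tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
    }) |>
    ungroup() |>
    mutate(label = lab) |>
    arrange(.data$chrom, .data$start)
}

#' Test genomic points for membership in an interval set
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions
#'   (VCF convention; converted internally).
#' @param intervals Interval table from [read_regions()].
#' @return Logical vector: `TRUE` where the position falls inside any interval.
#' @export
points_in_regions <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  chrom <- norm_chrom(chrom)
  hit <- rep(FALSE, length(pos))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    sub <- intervals[intervals$chrom == chr, ]
    if (nrow(sub) == 0) next
    q <- bed_to_iranges(vcf_pos_to_bed(pos[idx]))
    ov <- IRanges::overlapsAny(q, bed_to_iranges(sub))
    hit[idx] <- ov
  }
  hit
}

# Any-overlap test between an interval tibble `x` and a region set; returns a
# logical per row of x.
intervals_overlap_any <- function(x, intervals) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (chr in unique(x$chrom)) {
    idx <- which(x$chrom == chr)
    sub <- intervals[intervals$chrom == chr, ]
    if (nrow(sub) == 0) next
    out[idx] <- IRanges::overlapsAny(bed_to_iranges(x[idx, ]),
                                     bed_to_iranges(sub))
  }
  out
}

# List overlapping labels (e.g. gene names) for each row of x.
interval_hits <- function(x, intervals) {
  if (nrow(x) == 0) return(list())
  if (nrow(intervals) == 0) return(rep(list(character()), nrow(x)))
  out <- rep(list(character()), nrow(x))
  for (chr in unique(x$chrom)) {
    idx <- which(x$chrom == chr)
    sub <- intervals[intervals$chrom == chr, ]
    if (nrow(sub) == 0) next
    ov <- IRanges::findOverlaps(bed_to_iranges(x[idx, ]), bed_to_iranges(sub))
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
      out[[idx[i]]] <- unique(sub$label[sh[qh == i]])
    }
  }
  out
}

# "chr1" and "1" refer to the same chromosome everywhere in the package.
norm_chrom <- function(x) {
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

is_chrx <- function(chrom) norm_chrom(chrom) %in% c("chrX", "chrx")
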