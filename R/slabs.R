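# Slab detection: contiguous runs of high histone-mark signal of at
# least ~1 kb, as opposed to point peaks.

#' Automatic slab threshold: background/high-signal midpoint
#'
#' Estimates the typical background level as the median of the nonzero
#' per-base values and the saturating high-signal level as an extreme
#' upper quantile, and returns their geometric mean. For a track whose
#' signal is a mixture of a low background and much higher slab-level
#' coverage, this lands between the two modes regardless of what
#' fraction of the genome the slabs occupy — unlike a single upper
#' quantile, which falls inside the slab signal distribution (and
#' fragments calls) as soon as slabs cover more than its tail fraction.
#'
#' @param track A `coverage_track`.
#' @param high_quantile Quantile of nonzero values taken as the
#'   high-signal level.
#' @return Threshold in track units.
#' @export
slab_threshold <- function(track, high_quantile = 0.999) {
  v <- unlist(lapply(track$values, function(x) x[x > 0]), use.names = FALSE)
  if (length(v) == 0) abort("track has no nonzero values")
  sqrt(median(v) * unname(quantile(v, high_quantile)))
}

#' Call slab domains on a coverage track
#'
#' A slab is a maximal run of bases with signal at or above `threshold`,
#' after merging runs separated by sub-threshold gaps of at most
#' `max_gap` bp (linker-scale smoothing of MNase sampling gaps), kept
#' only when the merged length reaches `min_length` (default 1 kb —
#' several nucleosomes clustered together rather than a single peak).
#'
#' The signal threshold is deliberately a required parameter: "high" is a
#' property of the library's units. [track_quantile()] provides a
#' portable default (an upper quantile of nonzero signal).
#'
#' @param track A `coverage_track`.
#' @param threshold Signal threshold (track units, > 0).
#' @param min_length Minimum merged slab length (bp).
#' @param max_gap Maximum sub-threshold gap merged into a slab (bp).
#' @return Tibble of strandless slab calls, sorted and non-overlapping:
#'   chrom, start, end, length, mean_signal, max_signal.
#' @export
call_slabs <- function(track, threshold, min_length = 1000, max_gap = 100) {
  if (threshold <= 0) abort("`threshold` must be > 0")
  if (min_length < 1 || max_gap < 0) abort("invalid slab parameters")
  out <- list()
  for (cm in names(track$values)) {
    v <- track$values[[cm]]
    r <- rle(v >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    rs <- starts[r$values]; re <- ends[r$values]
    if (length(rs) == 0) next
    # merge supra-threshold runs across gaps <= max_gap
    if (length(rs) > 1) {
      gap <- rs[-1] - re[-length(re)]
      grp <- cumsum(c(0L, as.integer(gap > max_gap)))
    } else grp <- 0L
    ms <- tapply(rs, grp, min)
    me <- tapply(re, grp, max)
    keep <- (me - ms) >= min_length
    if (!any(keep)) next
    ms <- ms[keep]; me <- me[keep]
    out[[cm]] <- tibble(
      chrom = cm, start = as.integer(ms), end = as.integer(me),
      length = as.integer(me - ms),
      mean_signal = vapply(seq_along(ms), function(j) mean(v[(ms[j] + 1):me[j]]), numeric(1)),
      max_signal = vapply(seq_along(ms), function(j) max(v[(ms[j] + 1):me[j]]), numeric(1))
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), mean_signal = numeric(), max_signal = numeric()))
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

#' Annotate regions with slab presence (the M flag)
#'
#' For each query region, `m` is TRUE iff some slab overlaps it by at
#' least `min_overlap` bases (half-open arithmetic: a slab ending where
#' the region starts does not overlap). `overlap_bp` reports the largest
#' single-slab overlap.
#'
#' @param regions Tibble with chrom, start, end (0-based half-open);
#'   other columns pass through.
#' @param slabs Slab calls from [call_slabs()].
#' @param min_overlap Minimum overlap (bp) to set the flag.
#' @return `regions` with logical `m` and numeric `overlap_bp` columns.
#' @export
annotate_regions <- function(regions, slabs, min_overlap = 1) {
  ov <- numeric(nrow(regions))
  for (cm in unique(regions$chrom)) {
    qi <- which(regions$chrom == cm)
    si <- which(slabs$chrom == cm)
    if (length(si) == 0) next
    q <- IRanges::IRanges(start = regions$start[qi] + 1L, end = regions$end[qi])
    s <- IRanges::IRanges(start = slabs$start[si] + 1L, end = slabs$end[si])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                            s[S4Vectors::subjectHits(hits)]))
    best <- tapply(w, S4Vectors::queryHits(hits), max)
    ov[qi[as.integer(names(best))]] <- as.numeric(best)
  }
  mutate(regions, m = ov >= min_overlap, overlap_bp = ov)
}

#' @rdname annotate_regions
#' @description `region_has_slab()` is the scalar form: TRUE iff any slab
#'   overlaps the single given region by at least `min_overlap` bp.
#' @param chrom,start,end A single query interval.
#' @export
region_has_slab <- function(slabs, chrom, start, end, min_overlap = 1) {
  annotate_regions(tibble(chrom = chrom, start = start, end = end),
                   slabs, min_overlap)$m[1]
}

#' Write slab calls as BED4 (name column = mean signal)
#' @param slabs Slab calls.
#' @param path Output path.
#' @export
write_slab_bed <- function(slabs, path) {
  readr::write_tsv(tibble(chrom = slabs$chrom, start = slabs$start,
                          end = slabs$end, name = signif6(slabs$mean_signal)),
                   path, col_names = FALSE)
  invisible(path)
}
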