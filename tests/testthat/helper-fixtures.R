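# Fixture builders and independent oracles shared across tests.
# Everything is generated in code; no binary fixtures.

library(dplyr)

# write a GTF from 1-based closed exon coordinates (independent of
# slabir's own writer, so parser tests don't go through the code under test)
write_mini_gtf <- function(path, chrom, start1, end1, strand, gene_id,
                           transcript_id, type = "lncRNA") {
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_type "%s";',
    chrom, start1, end1, strand, gene_id, transcript_id, type)
  writeLines(lines, path)
  path
}

# coverage_track from raw per-chromosome vectors
make_track <- function(...) {
  vals <- list(...)
  cs <- setNames(vapply(vals, length, numeric(1)), names(vals))
  tr <- slabir::empty_track(cs)
  for (cm in names(vals)) tr$values[[cm]] <- as.numeric(vals[[cm]])
  tr
}

# brute-force scanline slab caller: explicit base-by-base state machine,
# structurally independent of the rle-based implementation
brute_slabs <- function(v, threshold, min_length, max_gap) {
  above <- which(v >= threshold)
  if (length(above) == 0) return(data.frame(start = integer(), end = integer()))
  runs <- list()
  rs <- above[1]; prev <- above[1]
  for (p in above[-1]) {
    if (p - prev > 1) { runs[[length(runs) + 1]] <- c(rs, prev); rs <- p }
    prev <- p
  }
  runs[[length(runs) + 1]] <- c(rs, prev)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= max_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else merged[[length(merged) + 1]] <- r
  }
  out <- do.call(rbind, merged)
  keep <- (out[, 2] - out[, 1] + 1) >= min_length
  # convert 1-based inclusive indices to 0-based half-open coordinates
  data.frame(start = out[keep, 1] - 1L, end = out[keep, 2])
}

# brute-force all-pairs half-open overlap flags
brute_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# small simulation spec for fast tests; ... overrides the tiny defaults
tiny_spec <- function(seed = 42, ...) {
  args <- list(n_chroms = 1, chrom_length = 8e5, n_lncrna = 20, n_mrna = 5,
               n_surveyed = 20, n_tags = 2e4, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  if (!"n_surveyed" %in% names(over) && "n_lncrna" %in% names(over)) {
    args$n_surveyed <- over$n_lncrna
  }
  do.call(slabir::sim_spec, args)
}
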