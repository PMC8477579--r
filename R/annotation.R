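# Exon/intron set construction and the stratifications the metagene
# profiles are anchored on.

models_exons <- function(models) {
  if (is.data.frame(models)) return(as_tibble(models))
  if (is.list(models) && !is.null(models$exons)) return(as_tibble(models$exons))
  abort("expected a gene_models object or an exon data frame")
}

# per-transcript gap to the adjacent exon in transcription direction
add_adjacent_gaps <- function(exons) {
  exons %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$exon_index, .by_group = TRUE) %>%
    mutate(
      .gap_prev = if_else(.data$strand == "+",
                          .data$start - lag(.data$end),
                          lag(.data$start) - .data$end),
      .gap_next = if_else(.data$strand == "+",
                          lead(.data$start) - .data$end,
                          .data$start - lead(.data$end)),
      upstream_gap = .data$.gap_prev,
      downstream_gap = .data$.gap_next
    ) %>%
    select(-".gap_prev", -".gap_next") %>%
    ungroup()
}

#' Select internal exons
#'
#' Internal exons are those that are neither first nor last in their
#' transcript (`1 < exon_index < n_exons`). "Internal" is judged per
#' transcript, then records sharing exact coordinates across isoforms are
#' collapsed to one (the first transcript id is retained), so an exon that
#' is internal in one isoform but terminal in another is kept. Gaps to the
#' adjacent exons (in transcription direction) are populated.
#'
#' @param models A `gene_models` object or an exon tibble.
#' @param biotype Optional filter: `"lncRNA"` or `"mRNA"`; `NULL` keeps both.
#' @return Tibble of internal exon records with `upstream_gap` and
#'   `downstream_gap` columns (bp to the adjacent exon).
#' @export
internal_exons <- function(models, biotype = NULL) {
  ex <- models_exons(models)
  if (!is.null(biotype)) ex <- filter(ex, .data$biotype == !!biotype)
  ex %>%
    add_adjacent_gaps() %>%
    filter(.data$exon_index > 1, .data$exon_index < .data$n_exons) %>%
    distinct(.data$chrom, .data$start, .data$end, .data$strand, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$start)
}

#' Derive non-overlapping introns
#'
#' For every transcript, the gaps between consecutive exons are candidate
#' introns, indexed in transcription direction (`intron_index = 1` is the
#' intron after the first exon). A candidate is discarded when it overlaps
#' any exon of any transcript of any gene, leaving the set of
#' non-overlapping introns; coordinate-identical survivors are
#' deduplicated (first transcript retained).
#'
#' @param models A `gene_models` object.
#' @return Tibble with columns chrom, start, end, strand, gene_id,
#'   transcript_id, intron_index, length, is_first, biotype.
#' @export
nonoverlapping_introns <- function(models) {
  ex <- models_exons(models)
  introns <- ex %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(.next_start = lead(.data$start)) %>%
    filter(!is.na(.data$.next_start)) %>%
    mutate(
      i_start = .data$end,
      i_end = .data$.next_start,
      # genomic-order gap j of k sits after exon j; on minus strand the
      # transcription-direction ordinal counts from the right
      .gi = row_number(),
      intron_index = if_else(.data$strand == "+", .data$.gi, n() - .data$.gi + 1L)
    ) %>%
    ungroup() %>%
    transmute(
      chrom = .data$chrom, start = .data$i_start, end = .data$i_end,
      strand = .data$strand, gene_id = .data$gene_id,
      transcript_id = .data$transcript_id,
      intron_index = as.integer(.data$intron_index),
      length = .data$end - .data$start,
      is_first = .data$intron_index == 1L,
      biotype = .data$biotype
    )
  if (any(introns$length <= 0)) abort("zero-length intron implies malformed transcript")
  # drop introns overlapping any exon anywhere
  hit <- overlaps_any(introns, ex)
  introns %>%
    filter(!hit) %>%
    distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$start)
}

# TRUE per query row iff it overlaps (>= 1 bp, half-open) any subject row
# on the same chromosome
overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  for (cm in unique(query$chrom)) {
    qi <- which(query$chrom == cm)
    si <- which(subject$chrom == cm)
    if (length(si) == 0) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    out[qi] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Keep exons isolated from their neighbours
#'
#' Retains exons separated from both adjacent exons by at least `min_gap`
#' bp ("at least" is inclusive: a gap of exactly `min_gap` survives).
#'
#' @param exons Tibble from [internal_exons()] (gaps populated).
#' @param min_gap Minimum gap to each adjacent exon (bp).
#' @return Filtered tibble.
#' @export
filter_isolated_exons <- function(exons, min_gap = 500) {
  filter(exons,
         !is.na(.data$upstream_gap), !is.na(.data$downstream_gap),
         .data$upstream_gap >= min_gap, .data$downstream_gap >= min_gap)
}

#' Drop the leading exons of each transcript
#'
#' Removes exons with `exon_index <= k`; `k = 2` removes first and second
#' exons, `k = 0` is the identity.
#'
#' @param exons Exon tibble with `exon_index`.
#' @param k Number of leading exons to drop.
#' @export
drop_leading_exons <- function(exons, k = 2) {
  filter(exons, .data$exon_index > k)
}

#' Partition first introns by length
#'
#' First introns (`is_first`) are split at `cutoff` bp; ties go to the
#' long group (the length filter elsewhere is "at least", so a single
#' inclusive boundary rule is used throughout). Non-first introns are
#' excluded from both groups.
#'
#' @param introns Intron tibble from [nonoverlapping_introns()].
#' @param cutoff Length cutoff (bp).
#' @return Named list with tibbles `short` (length < cutoff) and `long`
#'   (length >= cutoff).
#' @export
partition_first_introns <- function(introns, cutoff = 500) {
  fi <- filter(introns, .data$is_first)
  list(short = filter(fi, .data$length < cutoff),
       long = filter(fi, .data$length >= cutoff))
}

#' Per-exon GC content from a genome FASTA
#'
#' @param exons Exon tibble.
#' @param genome Path to a FASTA whose sequence names match `chrom`, or a
#'   `Biostrings::DNAStringSet`.
#' @return `exons` with a `gc` column (fraction G+C over the exon).
#' @export
exon_gc <- function(exons, genome) {
  seqs <- if (inherits(genome, "DNAStringSet")) genome
          else Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  miss <- setdiff(unique(exons$chrom), names(seqs))
  if (length(miss) > 0) {
    abort(sprintf("chromosome(s) missing from genome: %s", paste(miss, collapse = ", ")))
  }
  oob <- exons$end > Biostrings::width(seqs)[match(exons$chrom, names(seqs))]
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf("exon %s:%d-%d extends beyond genome sequence",
                  exons$chrom[i], exons$start[i], exons$end[i]))
  }
  gc <- vapply(seq_len(nrow(exons)), function(i) {
    s <- Biostrings::subseq(seqs[[exons$chrom[i]]], exons$start[i] + 1L, exons$end[i])
    sum(Biostrings::letterFrequency(s, c("G", "C"))) / length(s)
  }, numeric(1))
  mutate(exons, gc = gc)
}

#' Partition exons at the median GC content
#'
#' GC fraction is computed per exon over its interval and the set is split
#' at the median of the input set: `low` holds gc < median, `high` holds
#' gc >= median. The median split is parameter-free and yields two
#' near-equal groups.
#'
#' @inheritParams exon_gc
#' @return Named list of tibbles `low` and `high`, each with a `gc` column.
#' @export
partition_exons_by_gc <- function(exons, genome) {
  ex <- exon_gc(exons, genome)
  m <- median(ex$gc)
  list(low = filter(ex, .data$gc < m), high = filter(ex, .data$gc >= m))
}
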