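# Intron retention from RNA-seq coverage: a bounded per-intron retention
# ratio and the retained / non-retained dichotomy (any nonzero intronic
# coverage relative to its flanking exons counts as retention).

#' Per-intron retention ratio
#'
#' `sir_ratio = intron_depth / (intron_depth + mean(flank exon depths))`,
#' a bounded, scale-free score in the unit interval: 0 when the intron has no
#' coverage, 0.5 when intron and exons are equally covered (fully
#' retained at equal sampling), 1 when only the intron is covered. The
#' analysis downstream uses only the dichotomy `sir_ratio > 0`.
#'
#' @param intron_depth Mean per-base RNA coverage over the intron.
#' @param exon_depths Numeric vector of mean depths of the flanking
#'   exons (usually length 2).
#' @return Ratio between 0 and 1.
#' @export
sir_ratio <- function(intron_depth, exon_depths) {
  if (intron_depth < 0 || any(exon_depths < 0)) abort("depths must be non-negative")
  if (intron_depth == 0) return(0)
  intron_depth / (intron_depth + mean(exon_depths))
}

#' Classify introns as retained / non-retained
#'
#' Computes mean RNA-seq depth over each intron and its two flanking
#' exons (the exons with `exon_index` equal to `intron_index` and
#' `intron_index + 1` of the intron's source transcript), derives
#' [sir_ratio()], and calls an intron retained when `sir_ratio > 0` —
#' i.e., any level of retention. `min_depth` (default 0) optionally
#' requires the mean intronic depth to exceed a floor before a positive
#' ratio counts, guarding against single-read noise; the default
#' reproduces the strict any-coverage rule.
#'
#' Introns whose flanking exons cannot be resolved are skipped with a
#' warning.
#'
#' @param introns Intron tibble from [nonoverlapping_introns()].
#' @param rna A `coverage_track` of RNA-seq coverage.
#' @param models The `gene_models` the introns derive from.
#' @param min_depth Minimum mean intronic depth for a retained call.
#' @return Tibble of IR calls: the intron columns plus `intron_depth`,
#'   `flank_exon_depth`, `sir_ratio`, `retained`.
#' @export
classify_ir <- function(introns, rna, models, min_depth = 0) {
  ex <- models_exons(models)
  flank_key <- paste(ex$transcript_id, ex$exon_index)
  up_i <- match(paste(introns$transcript_id, introns$intron_index), flank_key)
  dn_i <- match(paste(introns$transcript_id, introns$intron_index + 1L), flank_key)
  unresolved <- is.na(up_i) | is.na(dn_i)
  if (any(unresolved)) {
    warn(sprintf("skipping %d intron(s) without resolvable flanking exons", sum(unresolved)))
    introns <- introns[!unresolved, , drop = FALSE]
    up_i <- up_i[!unresolved]; dn_i <- dn_i[!unresolved]
  }
  intron_depth <- region_mean_depths(rna, introns)
  up_depth <- region_mean_depths(rna, ex[up_i, , drop = FALSE])
  dn_depth <- region_mean_depths(rna, ex[dn_i, , drop = FALSE])
  flank <- (up_depth + dn_depth) / 2
  ratio <- vapply(seq_len(nrow(introns)), function(i) {
    sir_ratio(intron_depth[i], c(up_depth[i], dn_depth[i]))
  }, numeric(1))
  introns %>%
    mutate(intron_depth = intron_depth,
           flank_exon_depth = flank,
           sir_ratio = ratio,
           retained = ratio > 0 & intron_depth > min_depth)
}

#' Write IR calls as TSV
#' @param calls IR-call tibble from [classify_ir()].
#' @param path Output path.
#' @export
write_ir_tsv <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' Downstream profiles stratified by exon ordinal and IR class
#'
#' For each ordinal i in `indices`, anchors a downstream-side metagene
#' profile on exon i of the transcripts whose intron i belongs to the
#' requested IR class, exposing whether high histone-mark density tracks
#' the retained introns and is concentrated after the first exon.
#' Ordinals with no qualifying exon windows are omitted with a warning.
#'
#' @param track Histone-mark `coverage_track`.
#' @param models A `gene_models` object.
#' @param calls IR calls from [classify_ir()].
#' @param indices Exon ordinals to profile.
#' @param retained Logical: profile transcripts whose intron i is
#'   retained (TRUE) or non-retained (FALSE).
#' @param library_size Tag count of the histone-mark library.
#' @inheritParams metagene_profile
#' @return Row-bound `meta_profile` tibble with an `exon_index` column.
#' @export
profiles_by_intron_index <- function(track, models, calls, indices = 1:5,
                                     retained = TRUE, library_size,
                                     flank = 500, edge = 80) {
  ex <- models_exons(models)
  out <- list()
  for (i in indices) {
    tx <- calls$transcript_id[calls$intron_index == i & calls$retained == retained]
    anchors <- filter(ex, .data$transcript_id %in% tx, .data$exon_index == i)
    prof <- tryCatch(
      metagene_profile(track, anchors, side = "downstream",
                       flank = flank, edge = edge, library_size = library_size),
      error = function(e) NULL)
    if (is.null(prof)) {
      warn(sprintf("no qualifying exon windows at ordinal %d; omitted", i))
      next
    }
    out[[as.character(i)]] <- mutate(prof, exon_index = i)
  }
  bind_rows(out)
}
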