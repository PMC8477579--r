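# Exon-anchored metagene density profiles: 500 bp intronic flank plus
# 80 bp exon edge, averaged over exon windows and depth-normalized.

#' Genomic positions of one exon-anchored window
#'
#' Returns the 580 genomic positions (0-based) of the window on one side
#' of an exon, ordered in transcription direction so position 1 of the
#' series is always the most 5' end of the window. Upstream windows run
#' over the 500 intronic bases 5' of the exon then the first 80 exonic
#' bases; downstream windows over the last 80 exonic bases then the 500
#' intronic bases 3' of the exon. For minus-strand exons the genomic
#' order is reversed accordingly.
#'
#' Returns `NULL` (exclusion, not failure) when the exon is shorter than
#' `edge` or the window leaves the chromosome.
#'
#' @param chrom,start,end,strand Exon interval (0-based half-open).
#' @param side `"upstream"` or `"downstream"` (in transcription direction).
#' @param flank Intronic flank length (bp).
#' @param edge Exon-edge length (bp).
#' @param chrom_len Chromosome length (bp).
#' @return Integer vector of `flank + edge` genomic positions, or `NULL`.
#' @export
anchor_window <- function(chrom, start, end, strand,
                          side = c("upstream", "downstream"),
                          flank = 500, edge = 80, chrom_len = Inf) {
  side <- match.arg(side)
  if (end - start < edge) return(NULL)
  if (strand == "+") {
    pos <- if (side == "upstream") {
      c(seq.int(start - flank, start - 1L), seq.int(start, start + edge - 1L))
    } else {
      c(seq.int(end - edge, end - 1L), seq.int(end, end + flank - 1L))
    }
  } else {
    pos <- if (side == "upstream") {
      c(seq.int(end + flank - 1L, end), seq.int(end - 1L, end - edge))
    } else {
      c(seq.int(start + edge - 1L, start), seq.int(start - 1L, start - flank))
    }
  }
  if (pos[1] < 0 || pos[length(pos)] < 0 || max(pos[1], pos[length(pos)]) >= chrom_len) {
    return(NULL)
  }
  as.integer(pos)
}

profile_offsets <- function(side, flank, edge) {
  if (side == "upstream") c(seq.int(-flank, -1L), seq.int(1L, edge))
  else c(seq.int(-edge, -1L), seq.int(1L, flank))
}

#' Exon-anchored metagene density profile
#'
#' Averages track signal over the exon-anchored windows of one side of an
#' exon set and normalizes for the number of windows polled and the
#' library depth:
#' `density[i] = sum over windows of signal at position i / n_windows /
#' (library_size / 1e6)` — i.e., mean per-window signal in tags per
#' million. Exons shorter than `edge` or whose window leaves the
#' chromosome are excluded from that side.
#'
#' @param track A `coverage_track`.
#' @param exons Exon tibble (chrom, start, end, strand).
#' @param side `"upstream"` or `"downstream"`.
#' @param flank,edge Window geometry (bp); the default 500 + 80 gives the
#'   580-position series.
#' @param library_size Number of tags in the source library (normalization
#'   denominator); must be > 0.
#' @return A `meta_profile` tibble with columns `side`, `position`
#'   (1..flank+edge in transcription direction), `offset` (bp relative to
#'   the exon boundary; negative = before it), `region`
#'   (`"intron"`/`"exon"`), `density`, `n_windows`, `library_size`.
#' @export
metagene_profile <- function(track, exons, side = c("upstream", "downstream"),
                             flank = 500, edge = 80, library_size) {
  side <- match.arg(side)
  if (missing(library_size) || library_size <= 0) {
    abort("`library_size` must be a positive tag count")
  }
  width <- flank + edge
  sums <- numeric(width)
  n_windows <- 0L
  for (i in seq_len(nrow(exons))) {
    cm <- exons$chrom[i]
    if (!cm %in% names(track$values)) next
    pos <- anchor_window(cm, exons$start[i], exons$end[i], exons$strand[i],
                         side, flank, edge, track$chrom_sizes[[cm]])
    if (is.null(pos)) next
    sums <- sums + track$values[[cm]][pos + 1L]
    n_windows <- n_windows + 1L
  }
  if (n_windows == 0L) abort("no admissible exon windows for this side")
  off <- profile_offsets(side, flank, edge)
  exonic <- if (side == "upstream") off > 0 else off < 0
  out <- tibble(
    side = side,
    position = seq_len(width),
    offset = off,
    region = if_else(exonic, "exon", "intron"),
    density = sums / n_windows / (library_size / 1e6),
    n_windows = n_windows,
    library_size = library_size
  )
  class(out) <- c("meta_profile", class(out))
  out
}

#' Exonic enrichment over flanking introns
#'
#' Percentage increase of the mean density over all exonic positions of
#' the upstream and downstream profiles (2 x 80 = 160 positions for the
#' default geometry) relative to the mean over all intronic positions
#' (2 x 500 = 1000): `100 * (exon_mean / intron_mean - 1)`.
#'
#' @param up,down `meta_profile` tibbles for the upstream and downstream
#'   sides of the same exon set and library.
#' @return Enrichment in percent.
#' @export
exon_enrichment <- function(up, down) {
  both <- bind_rows(up, down)
  exon_mean <- mean(both$density[both$region == "exon"])
  intron_mean <- mean(both$density[both$region == "intron"])
  if (intron_mean == 0) abort("intronic mean density is zero; enrichment undefined")
  100 * (exon_mean / intron_mean - 1)
}

#' Write metagene profiles as TSV
#'
#' @param profiles A `meta_profile` tibble or a row-bound set of them
#'   (extra grouping columns pass through).
#' @param path Output path.
#' @export
write_profile_tsv <- function(profiles, path) {
  readr::write_tsv(as_tibble(profiles), path)
  invisible(path)
}

#' Plot metagene profiles
#'
#' Renders upstream/downstream series side by side with the conventional
#' central gap separating the two data series at the exon.
#'
#' @param profiles A row-bound tibble of `meta_profile` rows (both sides;
#'   extra columns such as `biotype` are mapped to colour if present).
#' @param colour Optional name of a column mapped to line colour.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, colour = NULL) {
  df <- as_tibble(profiles) %>%
    mutate(x = if_else(.data$side == "upstream", .data$offset,
                       .data$offset + max(.data$offset[.data$side == "upstream"]) + 60))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density))
  p <- if (!is.null(colour)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]],
                                        group = interaction(.data[[colour]], .data$side)))
  } else {
    p + ggplot2::geom_line(ggplot2::aes(group = .data$side))
  }
  p + ggplot2::labs(x = "position relative to exon boundaries (bp)",
                    y = "normalized density (per-window, tags/M)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_profiles
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @export
autoplot.meta_profile <- function(object, ...) plot_profiles(object)
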