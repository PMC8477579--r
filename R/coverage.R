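# Tag libraries and per-base coverage tracks.
#
# A coverage_track is a list of per-chromosome numeric vectors (one value
# per base, 0-based position i stored at R index i + 1) plus the
# chrom_sizes mapping. Plain dense vectors keep the window arithmetic
# trivial; simulated and test genomes are a few Mb, well within memory.

#' Read a sequencing-tag library (BED6 / tagAlign)
#'
#' Both dialects are 6-column BED-like text (tagAlign carries the read
#' sequence in column 4); coordinates are 0-based half-open. Gzipped
#' input is read transparently. Every record must carry a `+`/`-` strand
#' (column 6): the 3' tag extension is undefined without it.
#'
#' @param path Path to the tag file (plain or `.gz`).
#' @return A `tag_library`: list with `$tags` (tibble chrom, start, end,
#'   strand), `$total_tags` and `$source`.
#' @export
read_tags <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("empty tag file: %s", path))
  if (ncol(df) < 6) abort("tag records need 6 columns (chrom, start, end, name, score, strand)")
  strand <- df[[6]]
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf("%d tag record(s) lack a +/- strand", sum(!strand %in% c("+", "-"))))
  }
  tags <- tibble(chrom = df[[1]],
                 start = as.integer(df[[2]]),
                 end = as.integer(df[[3]]),
                 strand = strand)
  if (anyNA(tags$start) || anyNA(tags$end) || any(tags$start >= tags$end)) {
    abort("malformed tag coordinates (need integer start < end)")
  }
  structure(list(tags = tags, total_tags = nrow(tags), source = path),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %d tags from %s\n", x$total_tags, x$source))
  invisible(x)
}

as_tag_tibble <- function(tags) {
  if (inherits(tags, "tag_library")) tags$tags else as_tibble(tags)
}

#' Extend tags in the 3' direction
#'
#' Sequenced tags mark only the 5' end of the nucleosomal fragment; each
#' is extended to the expected fragment length in its 3' direction:
#' a `+` tag becomes `[start, start + length)`, a `-` tag
#' `[end - length, end)`, clipped to the chromosome.
#'
#' @param tags A `tag_library` or tag tibble.
#' @param length Extended fragment length (bp); 150 matches the
#'   mononucleosome expectation.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return Tibble chrom, start, end of the extended intervals.
#' @export
extend_tags <- function(tags, length = 150, chrom_sizes) {
  t <- as_tag_tibble(tags)
  check_chrom_sizes(chrom_sizes)
  len <- chrom_sizes[t$chrom]
  tibble(
    chrom = t$chrom,
    start = pmax(0, if_else(t$strand == "+", t$start, t$end - as.integer(length))),
    end = pmin(as.numeric(len), if_else(t$strand == "+", t$start + as.numeric(length),
                                        as.numeric(t$end)))
  )
}

new_coverage_track <- function(values, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(all(names(values) %in% names(chrom_sizes)),
            all(lengths(values) == chrom_sizes[names(values)]))
  structure(list(values = values, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$values, sum, numeric(1)))
  cat(sprintf("<coverage_track> %d chromosome(s), %.0f bp, total signal %.4g\n",
              length(x$chrom_sizes), sum(x$chrom_sizes), tot))
  invisible(x)
}

#' Empty (all-zero) coverage track
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @export
empty_track <- function(chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  vals <- lapply(chrom_sizes, function(n) numeric(n))
  new_coverage_track(vals, chrom_sizes)
}

#' Build a coverage track from extended tags
#'
#' Per-base value at position b is the number of extended tag intervals
#' containing b. Tags on chromosomes absent from `chrom_sizes` are
#' dropped with a warning.
#'
#' @param tags A `tag_library` or tag tibble.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param extension 3' extension length (bp); see [extend_tags()].
#' @return A `coverage_track`.
#' @export
build_coverage <- function(tags, chrom_sizes, extension = 150) {
  t <- as_tag_tibble(tags)
  check_chrom_sizes(chrom_sizes)
  unknown <- !t$chrom %in% names(chrom_sizes)
  if (any(unknown)) {
    warn(sprintf("dropping %d tag(s) on chromosome(s) absent from chrom_sizes",
                 sum(unknown)))
    t <- t[!unknown, , drop = FALSE]
  }
  iv <- extend_tags(t, length = extension, chrom_sizes = chrom_sizes)
  add_intervals(empty_track(chrom_sizes), iv$chrom, iv$start, iv$end, 1)
}

# add `value` over [start, end) intervals via a difference array
add_intervals <- function(track, chrom, start, end, value) {
  value <- rep_len(value, length(chrom))
  for (cm in unique(chrom)) {
    i <- chrom == cm
    n <- as.integer(track$chrom_sizes[[cm]])
    d <- numeric(n + 1L)
    s <- as.integer(start[i]) + 1L
    e <- as.integer(end[i]) + 1L
    v <- value[i]
    keep <- s <= n & e >= 1L & s < e
    s <- pmax(s[keep], 1L); e <- pmin(e[keep], n + 1L); v <- v[keep]
    if (length(s) > 0) {
      su <- rowsum(v, s); eu <- rowsum(v, e)
      d[as.integer(rownames(su))] <- d[as.integer(rownames(su))] + su[, 1]
      d[as.integer(rownames(eu))] <- d[as.integer(rownames(eu))] - eu[, 1]
    }
    track$values[[cm]] <- track$values[[cm]] + cumsum(d[seq_len(n)])
  }
  track
}

#' Read a bedGraph file into a coverage track
#'
#' Intervals are 0-based half-open; uncovered bases are 0. Overlapping
#' intervals make the per-base value ambiguous and raise an error.
#'
#' @param path bedGraph path (plain or `.gz`); `track`/comment lines are
#'   skipped.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  track <- empty_track(chrom_sizes)
  if (length(lines) == 0) return(track)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) abort("malformed bedGraph line (need 4 columns)")
  m <- matrix(unlist(lapply(f, `[`, 1:4)), ncol = 4, byrow = TRUE)
  df <- tibble(chrom = m[, 1], start = as.integer(m[, 2]),
               end = as.integer(m[, 3]), value = as.numeric(m[, 4]))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    abort("malformed bedGraph coordinates or value")
  }
  miss <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(miss) > 0) abort(sprintf("bedGraph chromosome(s) not in chrom_sizes: %s",
                                      paste(miss, collapse = ", ")))
  if (any(df$end > chrom_sizes[df$chrom]) || any(df$start < 0) || any(df$start >= df$end)) {
    abort("bedGraph interval out of bounds")
  }
  for (cm in unique(df$chrom)) {
    d <- df[df$chrom == cm, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort(sprintf("overlapping bedGraph intervals on %s: per-base value is ambiguous", cm))
    }
    v <- track$values[[cm]]
    for (j in seq_len(nrow(d))) v[(d$start[j] + 1L):d$end[j]] <- d$value[j]
    track$values[[cm]] <- v
  }
  track
}

track_runs <- function(values) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  tibble(start = ends - r$lengths, end = ends, value = r$values)
}

#' Write a coverage track as bedGraph or wiggle
#'
#' Output is run-length encoded; zero runs are omitted and values are
#' written with 6 significant digits. The wiggle dialect uses
#' `fixedStep ... step=1 span=1` blocks under a `track type=wiggle_0`
#' header and reloads to identical per-base values via [read_wiggle()].
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param dialect `"bedGraph"` or `"wiggle"`.
#' @export
write_track <- function(track, path, dialect = c("bedGraph", "wiggle")) {
  dialect <- match.arg(dialect)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (dialect == "wiggle") writeLines("track type=wiggle_0", con)
  for (cm in names(track$values)) {
    runs <- track_runs(track$values[[cm]])
    runs <- runs[runs$value != 0, , drop = FALSE]
    if (nrow(runs) == 0) next
    if (dialect == "bedGraph") {
      writeLines(sprintf("%s\t%d\t%d\t%s", cm, as.integer(runs$start),
                         as.integer(runs$end), signif6(runs$value)), con)
    } else {
      for (j in seq_len(nrow(runs))) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                           cm, as.integer(runs$start[j]) + 1L), con)
        writeLines(rep(signif6(runs$value[j]), runs$end[j] - runs$start[j]), con)
      }
    }
  }
  invisible(path)
}

signif6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

#' Read a fixedStep wiggle file
#'
#' Supports the `fixedStep` blocks emitted by [write_track()]
#' (step = span = 1); positions in wiggle are 1-based.
#'
#' @inheritParams read_bedgraph
#' @export
read_wiggle <- function(path, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  lines <- readr::read_lines(path, progress = FALSE)
  track <- empty_track(chrom_sizes)
  cm <- NULL; pos <- NA_integer_
  for (ln in lines) {
    if (grepl("^track", ln)) next
    if (grepl("^fixedStep", ln)) {
      cm <- sub('.*chrom=(\\S+).*', "\\1", ln)
      pos <- as.integer(sub(".*start=(\\d+).*", "\\1", ln))
      if (!cm %in% names(chrom_sizes)) abort(sprintf("wiggle chromosome not in chrom_sizes: %s", cm))
      next
    }
    if (is.null(cm)) abort("wiggle data line before fixedStep header")
    track$values[[cm]][pos] <- as.numeric(ln)
    pos <- pos + 1L
  }
  track
}

#' Mean per-base depth over an interval
#'
#' @param track A `coverage_track`.
#' @param chrom,start,end Interval (0-based half-open).
#' @return Arithmetic mean of per-base values over `[start, end)`.
#' @export
region_mean_depth <- function(track, chrom, start, end) {
  if (end <= start) abort("empty interval: end must exceed start")
  if (!chrom %in% names(track$values)) abort(sprintf("unknown chromosome: %s", chrom))
  v <- track$values[[chrom]]
  if (start < 0 || end > length(v)) abort("interval outside chromosome bounds")
  mean(v[(start + 1L):end])
}

# vectorised over a data frame of intervals
region_mean_depths <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    region_mean_depth(track, regions$chrom[i], regions$start[i], regions$end[i])
  }, numeric(1))
}

#' Quantile of the nonzero track values
#'
#' Helper for setting the slab threshold: the paper-scale "saturating"
#' signal level is operationalised as an upper quantile of the nonzero
#' per-base values.
#'
#' @param track A `coverage_track`.
#' @param q Quantile in (0, 1].
#' @export
track_quantile <- function(track, q = 0.99) {
  v <- unlist(lapply(track$values, function(x) x[x > 0]), use.names = FALSE)
  if (length(v) == 0) abort("track has no nonzero values")
  unname(quantile(v, q))
}
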