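# GTF reading/writing (GENCODE attribute dialect). Internally all
# coordinates are 0-based half-open; GTF is 1-based closed, converted at
# this boundary only.

extract_attr <- function(attrs, key) {
  pat <- paste0('.*', key, ' "([^"]*)".*')
  got <- grepl(paste0(key, ' "'), attrs, fixed = TRUE)
  ifelse(got, sub(pat, "\\1", attrs), NA_character_)
}

#' Parse gene models from a GTF file
#'
#' Reads exon features from a GENCODE-dialect GTF, groups them by
#' transcript, orders them 5'->3' in transcription direction, and labels
#' each transcript `lncRNA` or `mRNA`. Following the complement convention
#' used for the human annotation, "mRNA" here denotes every transcript
#' whose biotype is *not* in the lncRNA label set, not only protein-coding
#' ones. Coordinates are converted from GTF 1-based closed to 0-based
#' half-open.
#'
#' Transcripts whose exons overlap one another are rejected with a warning;
#' a malformed GTF line raises an error naming the line number.
#'
#' @param path Path to a GTF file (plain or gzipped).
#' @param chrom_sizes Named numeric vector of chromosome lengths. If `NULL`,
#'   lengths are inferred from the largest end coordinate per chromosome
#'   (with a warning), which is sufficient for window arithmetic on the
#'   annotation itself but not for coverage tracks.
#' @param lncrna_types Character vector of `transcript_type` /
#'   `gene_type` labels treated as lncRNA.
#' @return A `gene_models` object: a list with `$exons` (tibble with
#'   columns chrom, start, end, strand, gene_id, transcript_id, exon_index,
#'   n_exons, biotype) and `$chrom_sizes`.
#' @export
parse_gene_models <- function(path, chrom_sizes = NULL,
                              lncrna_types = c("lncRNA", "lincRNA")) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) abort("no feature lines found in GTF")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- idx[which(nf != 9)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  bad, nf[which(nf != 9)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  feature <- m[, 3]
  ex <- feature == "exon"
  if (!any(ex)) abort("GTF contains no exon features")
  start1 <- suppressWarnings(as.integer(m[ex, 4]))
  end1 <- suppressWarnings(as.integer(m[ex, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- idx[ex][which(is.na(start1) | is.na(end1))[1]]
    abort(sprintf("malformed GTF line %d: non-numeric coordinates", bad))
  }
  strand <- m[ex, 7]
  if (any(!strand %in% c("+", "-"))) {
    bad <- idx[ex][which(!strand %in% c("+", "-"))[1]]
    abort(sprintf("malformed GTF line %d: exon strand must be + or -", bad))
  }
  attrs <- m[ex, 9]
  exons <- tibble(
    chrom = m[ex, 1],
    start = start1 - 1L,   # to 0-based half-open
    end = end1,
    strand = strand,
    gene_id = extract_attr(attrs, "gene_id"),
    transcript_id = extract_attr(attrs, "transcript_id"),
    ttype = extract_attr(attrs, "transcript_type"),
    gtype = extract_attr(attrs, "gene_type")
  )
  if (anyNA(exons$gene_id) || anyNA(exons$transcript_id)) {
    abort("exon feature missing gene_id or transcript_id attribute")
  }
  if (any(exons$start >= exons$end)) {
    abort("exon with non-positive length in GTF")
  }
  exons <- exons %>%
    mutate(biotype = if_else(dplyr::coalesce(.data$ttype, .data$gtype, "") %in% lncrna_types,
                             "lncRNA", "mRNA")) %>%
    select(-"ttype", -"gtype")

  # order within transcript in transcription direction, assign exon_index
  exons <- exons %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(.overlap = n() > 1 && any(.data$start[-1] < .data$end[-n()])) %>%
    ungroup()
  if (any(exons$.overlap)) {
    bad_tx <- unique(exons$transcript_id[exons$.overlap])
    warn(sprintf("rejecting %d transcript(s) with overlapping exons: %s",
                 length(bad_tx), paste(head(bad_tx, 5), collapse = ", ")))
    exons <- filter(exons, !.data$.overlap)
  }
  exons <- exons %>%
    select(-".overlap") %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(n_exons = n(),
           exon_index = if (first(.data$strand) == "+") row_number()
                        else n() - row_number() + 1L) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)

  if (is.null(chrom_sizes)) {
    warn("no chrom_sizes supplied; inferring chromosome lengths from annotation extents")
    chrom_sizes <- tapply(exons$end, exons$chrom, max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  check_chrom_sizes(chrom_sizes)
  miss <- setdiff(unique(exons$chrom), names(chrom_sizes))
  if (length(miss) > 0) {
    abort(sprintf("chromosome(s) in GTF absent from chrom_sizes: %s",
                  paste(miss, collapse = ", ")))
  }
  out_of_bounds <- exons$end > chrom_sizes[exons$chrom]
  if (any(out_of_bounds)) {
    abort(sprintf("%d exon(s) extend beyond chromosome bounds", sum(out_of_bounds)))
  }
  structure(list(exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d exons, %d transcripts, %d genes on %d chromosome(s)\n",
              nrow(x$exons), dplyr::n_distinct(x$exons$transcript_id),
              dplyr::n_distinct(x$exons$gene_id), length(x$chrom_sizes)))
  tab <- x$exons %>% distinct(.data$transcript_id, .data$biotype) %>% count(.data$biotype)
  for (i in seq_len(nrow(tab))) cat(sprintf("  %s transcripts: %d\n", tab$biotype[i], tab$n[i]))
  invisible(x)
}

#' Write gene models back to GTF
#'
#' Emits one exon feature per record, converting internal 0-based
#' half-open coordinates back to GTF 1-based closed. Round-trips with
#' [parse_gene_models()].
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons %>% arrange(.data$chrom, .data$start, .data$transcript_id)
  lines <- sprintf(
    '%s\tslabir\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_type "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    if_else(ex$biotype == "lncRNA", "lncRNA", "protein_coding"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param x Data frame with columns chrom, start, end and optionally
#'   strand; a `name` and `score` column are used when present.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  bed <- tibble(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
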