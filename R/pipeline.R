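# Stage orchestration: file-in / file-out wrappers over the analysis
# functions, each writing a manifest of its inputs and parameters. A
# thin command-line wrapper over these lives in inst/cli/slabir.R.

write_manifest <- function(out_dir, command, params) {
  jsonlite::write_json(
    list(tool = "slabir", version = as.character(utils::packageVersion("slabir")),
         command = command, timestamp = format(Sys.time(), tz = "UTC"),
         params = params),
    file.path(out_dir, paste0(command, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the metagene profiling stage
#'
#' Reads gene models and one tag library, builds the coverage track with
#' 3' tag extension, and writes per-biotype upstream/downstream metagene
#' profile TSVs (and optionally a plot).
#'
#' @param gtf,tags,chrom_sizes Input paths.
#' @param out_dir Output directory (created if needed).
#' @param mark Label used in output filenames.
#' @param flank,edge,extension Window and extension geometry (bp).
#' @param isolated_only Apply the >= `min_gap` adjacent-exon isolation
#'   filter before profiling.
#' @param min_gap Isolation gap (bp), used when `isolated_only`.
#' @param drop_leading Drop exons with `exon_index <=` this count
#'   (0 = keep all).
#' @param plot Also write a profile plot (PDF).
#' @return Invisibly, the row-bound profile tibble.
#' @export
run_profile <- function(gtf, tags, chrom_sizes, out_dir, mark = "mark",
                        flank = 500, edge = 80, extension = 150,
                        isolated_only = FALSE, min_gap = 500,
                        drop_leading = 0, plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- read_chrom_sizes(chrom_sizes)
  models <- parse_gene_models(gtf, chrom_sizes = cs)
  lib <- read_tags(tags)
  track <- build_coverage(lib, cs, extension = extension)
  out <- list()
  for (bt in c("lncRNA", "mRNA")) {
    ex <- internal_exons(models, biotype = bt)
    if (drop_leading > 0) ex <- drop_leading_exons(ex, k = drop_leading)
    if (isolated_only) ex <- filter_isolated_exons(ex, min_gap = min_gap)
    if (nrow(ex) == 0) { warn(sprintf("no %s exons to profile", bt)); next }
    for (sd in c("upstream", "downstream")) {
      prof <- metagene_profile(track, ex, side = sd, flank = flank, edge = edge,
                               library_size = lib$total_tags)
      prof <- mutate(prof, biotype = bt, mark = mark)
      write_profile_tsv(prof, file.path(out_dir, sprintf("profile_%s_%s_%s.tsv",
                                                         mark, bt, sd)))
      out[[paste(bt, sd)]] <- prof
    }
  }
  all <- bind_rows(out)
  if (plot && nrow(all) > 0) {
    p <- plot_profiles(all, colour = "biotype")
    ggplot2::ggsave(file.path(out_dir, sprintf("profile_%s.pdf", mark)), p,
                    width = 8, height = 4)
  }
  write_manifest(out_dir, "profile",
                 list(gtf = gtf, tags = tags, chrom_sizes = chrom_sizes,
                      mark = mark, flank = flank, edge = edge,
                      extension = extension, isolated_only = isolated_only,
                      min_gap = min_gap, drop_leading = drop_leading))
  invisible(all)
}

#' Run the slab-calling stage
#'
#' Reads a histone-mark bedGraph track, calls slabs, and annotates the
#' query regions with the M flag.
#'
#' @param track_path bedGraph of histone-mark coverage.
#' @param regions_path BED of query regions (name in column 4).
#' @param chrom_sizes chrom.sizes path.
#' @param out_dir Output directory.
#' @param threshold Signal threshold; `NULL` uses the automatic
#'   background/high-signal midpoint of [slab_threshold()] (or
#'   [track_quantile()] when `threshold_quantile` is given).
#' @param threshold_quantile Optional quantile of nonzero values used as
#'   the threshold instead of the midpoint rule.
#' @param min_length,max_gap Slab geometry (bp).
#' @return Invisibly, list with `slabs` and `regions` (annotated).
#' @export
run_slabs <- function(track_path, regions_path, chrom_sizes, out_dir,
                      threshold = NULL, threshold_quantile = NULL,
                      min_length = 1000, max_gap = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- read_chrom_sizes(chrom_sizes)
  track <- read_bedgraph(track_path, cs)
  if (is.null(threshold)) {
    threshold <- if (!is.null(threshold_quantile)) track_quantile(track, threshold_quantile)
                 else slab_threshold(track)
  }
  slabs <- call_slabs(track, threshold, min_length = min_length, max_gap = max_gap)
  bed <- readr::read_tsv(regions_path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  bed <- tibble(chrom = bed[[1]], start = as.integer(bed[[2]]),
                end = as.integer(bed[[3]]),
                name = if (ncol(bed) >= 4) bed[[4]] else as.character(seq_len(nrow(bed))))
  ann <- annotate_regions(bed, slabs)
  write_slab_bed(slabs, file.path(out_dir, "slabs.bed"))
  readr::write_tsv(select(ann, "name", "chrom", "start", "end", "m", "overlap_bp"),
                   file.path(out_dir, "region_annotation.tsv"))
  write_manifest(out_dir, "slabs",
                 list(track = track_path, regions = regions_path,
                      chrom_sizes = chrom_sizes, threshold = threshold,
                      threshold_quantile = threshold_quantile,
                      min_length = min_length, max_gap = max_gap))
  invisible(list(slabs = slabs, regions = ann, threshold = threshold))
}

#' Run the intron-retention stage
#'
#' Reads gene models and RNA-seq coverage, derives non-overlapping
#' introns, and writes per-intron retention calls.
#'
#' @param gtf,rna,chrom_sizes Input paths.
#' @param out_dir Output directory.
#' @param min_depth Minimum mean intronic depth for a retained call
#'   (0 = any coverage counts).
#' @return Invisibly, the IR-call tibble.
#' @export
run_ir <- function(gtf, rna, chrom_sizes, out_dir, min_depth = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- read_chrom_sizes(chrom_sizes)
  models <- parse_gene_models(gtf, chrom_sizes = cs)
  track <- read_bedgraph(rna, cs)
  introns <- nonoverlapping_introns(models)
  calls <- classify_ir(introns, track, models, min_depth = min_depth)
  write_ir_tsv(calls, file.path(out_dir, "ir_calls.tsv"))
  write_manifest(out_dir, "ir",
                 list(gtf = gtf, rna = rna, chrom_sizes = chrom_sizes,
                      min_depth = min_depth))
  invisible(calls)
}

#' Run the association stage
#'
#' Joins the slab region annotation with IR calls by region name (the
#' region name must equal the IR call's gene id) — or takes four literal
#' cell counts — and writes the contingency report with chi-squared,
#' p-value, concordance and per-class intron summaries.
#'
#' @param region_annotation Path to the TSV written by [run_slabs()], or
#'   `NULL` when `cells` is given.
#' @param ir_calls Path to the TSV written by [run_ir()], or `NULL`.
#' @param out_dir Output directory.
#' @param cells Optional four counts (M+IR+, M+IR-, M-IR+, M-IR-)
#'   reproducing a printed table without tracks.
#' @return Invisibly, list with the `slab_ir_test` and (when computed
#'   from calls) the group summaries.
#' @export
run_associate <- function(region_annotation = NULL, ir_calls = NULL, out_dir,
                          cells = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- NULL
  if (!is.null(cells)) {
    test <- slab_ir_test_from_cells(cells)
  } else {
    ann <- readr::read_tsv(region_annotation, col_types = readr::cols(), progress = FALSE)
    calls <- readr::read_tsv(ir_calls, col_types = readr::cols(), progress = FALSE)
    merged <- dplyr::inner_join(ann, calls,
                                by = c("name" = "gene_id", "chrom" = "chrom"),
                                suffix = c(".region", ".intron"))
    unmatched <- setdiff(ann$name, merged$name)
    if (length(unmatched) > 0) {
      abort(sprintf("region id(s) without matching IR call: %s",
                    paste(head(unmatched, 10), collapse = ", ")))
    }
    # one surveyed intron per region: keep the intron inside the block
    merged <- merged %>%
      filter(.data$start.intron >= .data$start.region,
             .data$end.intron <= .data$end.region) %>%
      group_by(.data$name) %>% slice(1) %>% ungroup()
    test <- slab_ir_test(merged$m, merged$retained)
    summaries <- group_length_stats(
      transmute(merged, retained = .data$retained, length = .data$length,
                is_first = .data$is_first))
    readr::write_tsv(summaries, file.path(out_dir, "group_summaries.tsv"))
  }
  report <- glance(test)
  readr::write_tsv(tidy(test), file.path(out_dir, "contingency_cells.tsv"))
  readr::write_tsv(report, file.path(out_dir, "association_report.tsv"))
  jsonlite::write_json(as.list(report), file.path(out_dir, "association_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "associate",
                 list(region_annotation = region_annotation, ir_calls = ir_calls,
                      cells = cells))
  invisible(list(test = test, summaries = summaries))
}

#' Run the full pipeline on one dataset
#'
#' simulate (optional) -> profile -> slabs -> ir -> associate, with each
#' stage reading the previous stage's files, mirroring how the stages
#' compose on real data.
#'
#' @param data_dir Directory holding `models.gtf`, `chrom.sizes`,
#'   `nucleosome_tags.bed`, `h3k4me3.bedGraph`, `rna.bedGraph`,
#'   `regions.bed` (e.g. from [simulate_dataset()]).
#' @param out_dir Output directory.
#' @param threshold Slab threshold; `NULL` = automatic midpoint rule.
#' @return Invisibly, list of per-stage results.
#' @export
run_all <- function(data_dir, out_dir, threshold = NULL) {
  p <- function(f) file.path(data_dir, f)
  prof <- run_profile(p("models.gtf"), p("nucleosome_tags.bed"), p("chrom.sizes"),
                      out_dir, mark = "nucleosome")
  sl <- run_slabs(p("h3k4me3.bedGraph"), p("regions.bed"), p("chrom.sizes"),
                  out_dir, threshold = threshold)
  ir <- run_ir(p("models.gtf"), p("rna.bedGraph"), p("chrom.sizes"), out_dir)
  assoc <- run_associate(file.path(out_dir, "region_annotation.tsv"),
                         file.path(out_dir, "ir_calls.tsv"), out_dir)
  invisible(list(profiles = prof, slabs = sl, ir = ir, association = assoc))
}
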