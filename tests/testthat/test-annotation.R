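# Gene-model parsing and exon/intron set construction.

test_that("GTF coordinates convert to 0-based half-open and strand sets exon order", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_mini_gtf(gtf, rep("chr1", 3), c(101, 301, 501), c(200, 400, 600),
                 rep("+", 3), "g1", "t1")
  models <- suppressWarnings(parse_gene_models(gtf))
  expect_equal(nrow(models$exons), 3)
  expect_equal(models$exons$start, c(100, 300, 500))
  expect_equal(models$exons$end, c(200, 400, 600))
  expect_equal(models$exons$exon_index, 1:3)

  write_mini_gtf(gtf, rep("chr1", 3), c(101, 301, 501), c(200, 400, 600),
                 rep("-", 3), "g1", "t1")
  minus <- suppressWarnings(parse_gene_models(gtf))
  # transcription runs right to left: rightmost exon is exon 1
  expect_equal(minus$exons$exon_index[minus$exons$start == 500], 1L)
  expect_equal(minus$exons$exon_index[minus$exons$start == 100], 3L)
})

test_that("malformed GTF lines raise errors naming the line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    '# a comment',
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\tbroken-line'
  ), gtf)
  expect_error(parse_gene_models(gtf), "line 3")
})

test_that("transcripts with overlapping exons are rejected with a warning", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_mini_gtf(gtf, rep("chr1", 4), c(101, 150, 1001, 2001), c(200, 250, 1100, 2100),
                 rep("+", 4), c("g1", "g1", "g2", "g2"), c("t1", "t1", "t2", "t2"))
  expect_warning(models <- parse_gene_models(gtf, chrom_sizes = c(chr1 = 10000)),
                 "overlapping")
  expect_equal(unique(models$exons$transcript_id), "t2")
})

test_that("parsed transcript structure matches generator truth on a synthetic fixture", {
  spec <- tiny_spec(seed = 3)
  gm <- simulate_gene_models(spec)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm$models, gtf)
  reparsed <- parse_gene_models(gtf, chrom_sizes = gm$models$chrom_sizes)
  expect_equal(dplyr::n_distinct(reparsed$exons$transcript_id), nrow(gm$truth))
  counts <- reparsed$exons %>% count(.data$transcript_id) %>% arrange(.data$transcript_id)
  truth_counts <- gm$truth %>% arrange(.data$transcript_id)
  expect_equal(counts$n, truth_counts$n_exons)
  # round trip: identical exon coordinates and indices
  expect_equal(
    reparsed$exons %>% arrange(transcript_id, exon_index) %>%
      select(chrom, start, end, strand, exon_index, biotype),
    gm$models$exons %>% arrange(transcript_id, exon_index) %>%
      select(chrom, start, end, strand, exon_index, biotype)
  )
})

test_that("internal exon selection keeps middles only and dedupes shared coordinates", {
  ex3 <- tibble(chrom = "chr1", start = c(100, 300, 500), end = c(200, 400, 600),
                strand = "+", gene_id = "g1", transcript_id = "t1",
                biotype = "lncRNA", n_exons = 3L, exon_index = 1:3)
  got <- internal_exons(ex3)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 300)
  expect_equal(got$upstream_gap, 100)
  expect_equal(got$downstream_gap, 100)

  ex2 <- filter(ex3, exon_index < 3) %>% mutate(n_exons = 2L)
  expect_equal(nrow(internal_exons(ex2)), 0)

  # two isoforms share the internal exon -> one record, first transcript kept
  iso <- bind_rows(ex3, mutate(ex3, transcript_id = "t2"))
  got2 <- internal_exons(iso)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$transcript_id, "t1")
})

test_that("internal exon count is max(0, n - 2) per transcript before dedupe", {
  spec <- tiny_spec(seed = 5)
  gm <- simulate_gene_models(spec)
  got <- internal_exons(gm$models)
  expect_equal(nrow(got), sum(pmax(0, gm$truth$n_exons - 2)))
})

test_that("minus-strand internal exon gaps are measured in transcription direction", {
  ex <- tibble(chrom = "chr1", start = c(100, 500, 1000), end = c(200, 600, 1100),
               strand = "-", gene_id = "g1", transcript_id = "t1",
               biotype = "lncRNA", n_exons = 3L, exon_index = 3:1)
  got <- internal_exons(ex)
  # upstream (5', to the right): 1000 - 600 = 400; downstream: 500 - 200 = 300
  expect_equal(got$upstream_gap, 400)
  expect_equal(got$downstream_gap, 300)
})

test_that("intron derivation yields inter-exon gaps with transcript-direction ordinals", {
  ex <- tibble(chrom = "chr1", start = c(100, 500), end = c(200, 600),
               strand = "+", gene_id = "g1", transcript_id = "t1",
               biotype = "lncRNA", n_exons = 2L, exon_index = 1:2)
  got <- nonoverlapping_introns(list(exons = ex, chrom_sizes = c(chr1 = 1000)))
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end, got$length), c(200, 500, 300))
  expect_true(got$is_first)

  # an intron spanning an exon of a second isoform is excluded
  iso2 <- tibble(chrom = "chr1", start = 300, end = 350, strand = "+",
                 gene_id = "g1", transcript_id = "t2", biotype = "lncRNA",
                 n_exons = 1L, exon_index = 1L)
  got2 <- nonoverlapping_introns(list(exons = bind_rows(ex, iso2),
                                      chrom_sizes = c(chr1 = 1000)))
  expect_equal(nrow(got2), 0)
})

test_that("non-overlapping intron set equals the brute-force overlap scan", {
  spec <- tiny_spec(seed = 11)
  gm <- simulate_gene_models(spec)
  ex <- gm$models$exons
  got <- nonoverlapping_introns(gm$models)
  # oracle: every per-transcript gap, kept iff no all-pairs exon overlap
  cand <- ex %>% group_by(transcript_id) %>% arrange(start, .by_group = TRUE) %>%
    mutate(nstart = lead(start)) %>% filter(!is.na(nstart)) %>% ungroup() %>%
    transmute(chrom, start = end, end = nstart)
  keep <- !brute_overlaps_any(cand, ex)
  oracle <- cand[keep, ] %>% distinct(chrom, start, end) %>% arrange(chrom, start)
  expect_equal(got %>% select(chrom, start, end) %>% arrange(chrom, start),
               oracle)
})

test_that("isolation filter boundary is inclusive and survivor count matches a hand count", {
  base <- tibble(chrom = "chr1", start = 1000, end = 1150, strand = "+",
                 gene_id = "g", transcript_id = "t", biotype = "lncRNA",
                 n_exons = 3L, exon_index = 2L)
  gaps <- list(c(499, 800), c(500, 500), c(501, 499), c(1000, 1000), c(0, 5000))
  exons <- bind_rows(lapply(seq_along(gaps), function(i) {
    mutate(base, transcript_id = paste0("t", i),
           upstream_gap = gaps[[i]][1], downstream_gap = gaps[[i]][2])
  }))
  got <- filter_isolated_exons(exons, min_gap = 500)
  expect_equal(nrow(got), 2)  # hand count: (500,500) and (1000,1000)
  expect_true(all(got$upstream_gap >= 500 & got$downstream_gap >= 500))
})

test_that("leading-exon removal respects k and k = 0 is the identity", {
  ex <- tibble(exon_index = 1:5)
  expect_equal(drop_leading_exons(ex, k = 2)$exon_index, 3:5)
  expect_equal(drop_leading_exons(ex, k = 0), ex)
})

test_that("first-intron length partition puts the boundary in the long group", {
  introns <- tibble(length = c(192, 354, 2181, 500, 700),
                    is_first = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  parts <- partition_first_introns(introns, cutoff = 500)
  expect_setequal(parts$short$length, c(192, 354))
  expect_setequal(parts$long$length, c(2181, 500))  # 500 is "at least" -> long
  expect_false(700 %in% c(parts$short$length, parts$long$length))
})

test_that("GC computation and median split match hand-computed values", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "GGCCAATTACGTACGGGGCCCCAATT"))
  exons <- tibble(chrom = "chr1",
                  start = c(0, 4, 8, 12, 16, 20), end = c(4, 8, 12, 16, 20, 24),
                  strand = "+")
  got <- exon_gc(exons, seqs)
  # hand-read 4-mers: GGCC, AATT, ACGT, ACGG, GGCC, CCAA
  expect_equal(got$gc, c(1, 0, 0.5, 0.75, 1, 0.5))
  parts <- partition_exons_by_gc(exons, seqs)
  # median gc = 0.625; low = gc < median {0, 0.5, 0.5}, high = {0.75, 1, 1}
  expect_equal(nrow(parts$low), 3)
  expect_equal(nrow(parts$high), 3)
  expect_true(all(parts$high$gc >= 0.625) && all(parts$low$gc < 0.625))
  expect_error(exon_gc(mutate(exons, end = end + 100), seqs), "beyond")
})

test_that("strand flip leaves intron lengths and partition sizes unchanged", {
  spec <- tiny_spec(seed = 19)
  gm <- simulate_gene_models(spec)
  L <- gm$models$chrom_sizes[["chr1"]]
  flipped <- gm$models
  flipped$exons <- gm$models$exons %>%
    mutate(s2 = L - end, e2 = L - start,
           strand = if_else(strand == "+", "-", "+"),
           start = s2, end = e2) %>%
    select(-s2, -e2) %>%
    group_by(transcript_id) %>% arrange(start, .by_group = TRUE) %>%
    mutate(exon_index = if (first(strand) == "+") row_number()
                        else dplyr::n() - row_number() + 1L) %>%
    ungroup()
  a <- nonoverlapping_introns(gm$models)
  b <- nonoverlapping_introns(flipped)
  expect_equal(sort(a$length), sort(b$length))
  expect_equal(sort(a$intron_index), sort(b$intron_index))
  pa <- partition_first_introns(a); pb <- partition_first_introns(b)
  expect_equal(nrow(pa$short), nrow(pb$short))
  expect_equal(nrow(pa$long), nrow(pb$long))
  ia <- internal_exons(gm$models); ib <- internal_exons(flipped)
  expect_equal(nrow(ia), nrow(ib))
  expect_equal(nrow(filter_isolated_exons(ia)), nrow(filter_isolated_exons(ib)))
})
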