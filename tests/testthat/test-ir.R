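# Intron-retention scoring and classification.

test_that("retention ratio follows its defining cases", {
  expect_equal(sir_ratio(0, c(10, 10)), 0)            # no intronic coverage
  expect_equal(sir_ratio(5, c(5, 5)), 0.5)            # uniform coverage
  expect_equal(sir_ratio(2, c(10, 6)), 0.2)           # 2 / (2 + 8)
  expect_equal(sir_ratio(3, c(0, 0)), 1)              # intron-only coverage
  expect_error(sir_ratio(-1, c(1, 1)), "non-negative")
})

test_that("retention ratio is bounded, monotone in intron depth, and scale-free", {
  set.seed(41)
  for (i in 1:50) {
    d <- runif(1, 0, 50); e <- runif(2, 0, 50)
    r <- sir_ratio(d, e)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_gte(sir_ratio(d + 1, e), r)                 # monotone
    c0 <- runif(1, 0.1, 9)
    expect_equal(sir_ratio(c0 * d, c0 * e), r)         # scale invariance
  }
})

test_that("classification recovers generator truth exactly on deterministic coverage", {
  spec <- tiny_spec(seed = 43)
  gm <- simulate_gene_models(spec)
  rna <- simulate_rnaseq_coverage(gm$models, gm$truth, spec)
  introns <- nonoverlapping_introns(gm$models)
  calls <- classify_ir(introns, rna$track, gm$models)
  truth <- filter(gm$truth, surveyed)
  got <- calls$retained[match(paste(truth$transcript_id, truth$surveyed_intron_index),
                              paste(calls$transcript_id, calls$intron_index))]
  expect_equal(got, truth$ir_truth)
  # non-surveyed introns are all non-retained
  surveyed_key <- paste(truth$transcript_id, truth$surveyed_intron_index)
  others <- calls[!paste(calls$transcript_id, calls$intron_index) %in% surveyed_key, ]
  expect_false(any(others$retained))
})

test_that("zero or exon-restricted RNA coverage yields zero retained introns", {
  spec <- tiny_spec(seed = 44)
  gm <- simulate_gene_models(spec)
  introns <- nonoverlapping_introns(gm$models)
  zero <- empty_track(gm$models$chrom_sizes)
  expect_false(any(classify_ir(introns, zero, gm$models)$retained))

  exonly <- empty_track(gm$models$chrom_sizes)
  ex <- gm$models$exons
  for (i in seq_len(nrow(ex))) {
    exonly$values[[ex$chrom[i]]][(ex$start[i] + 1):ex$end[i]] <- 8
  }
  calls <- classify_ir(introns, exonly, gm$models)
  expect_false(any(calls$retained))
  expect_true(all(calls$flank_exon_depth == 8))
})

test_that("classification stays accurate under Poisson noise at 20x exon depth", {
  spec <- tiny_spec(seed = 45, n_lncrna = 60, n_surveyed = 60, chrom_length = 2e6,
                    rna_exon_depth_range = c(20, 20))
  gm <- simulate_gene_models(spec)
  rna <- simulate_rnaseq_coverage(gm$models, gm$truth, spec,
                                  poisson = TRUE, noise_rate = 0.02)
  introns <- nonoverlapping_introns(gm$models)
  # a small depth floor guards against spurious single-read coverage
  calls <- classify_ir(introns, rna$track, gm$models, min_depth = 0.5)
  truth <- filter(gm$truth, surveyed)
  got <- calls$retained[match(paste(truth$transcript_id, truth$surveyed_intron_index),
                              paste(calls$transcript_id, calls$intron_index))]
  sens <- mean(got[truth$ir_truth]); spec_ <- mean(!got[!truth$ir_truth])
  expect_gte(sens, 0.95)
  expect_gte(spec_, 0.95)
})

test_that("skipping unresolvable flanking exons warns and drops only those introns", {
  spec <- tiny_spec(seed = 46)
  gm <- simulate_gene_models(spec)
  introns <- nonoverlapping_introns(gm$models)
  broken <- mutate(introns, transcript_id = if_else(dplyr::row_number() == 1,
                                                    "missing", transcript_id))
  rna <- empty_track(gm$models$chrom_sizes)
  expect_warning(calls <- classify_ir(broken, rna, gm$models), "skipping 1 intron")
  expect_equal(nrow(calls), nrow(introns) - 1)
})

test_that("ordinal-stratified profiles partition windows and flag the retained contrast", {
  spec <- tiny_spec(seed = 47, n_lncrna = 40, n_surveyed = 40, chrom_length = 1.6e6,
                    p_first_given_ir = 1, p_first_given_noir = 0)
  gm <- simulate_gene_models(spec)
  rna <- simulate_rnaseq_coverage(gm$models, gm$truth, spec)
  introns <- nonoverlapping_introns(gm$models)
  calls <- classify_ir(introns, rna$track, gm$models)
  h3k <- simulate_nucleosome_tags(gm$models, gm$truth, spec, mark = "H3K4me3")
  track <- build_coverage(h3k, gm$models$chrom_sizes)

  ret <- suppressWarnings(
    profiles_by_intron_index(track, gm$models, calls, indices = 1:3,
                             retained = TRUE, library_size = h3k$total_tags))
  non <- suppressWarnings(
    profiles_by_intron_index(track, gm$models, calls, indices = 1:3,
                             retained = FALSE, library_size = h3k$total_tags))
  # windows partition: retained + non-retained = all anchored exons per ordinal
  all_prof <- suppressWarnings(
    profiles_by_intron_index(track, gm$models,
                             mutate(calls, retained = TRUE),
                             indices = 1:3, retained = TRUE,
                             library_size = h3k$total_tags))
  for (i in intersect(unique(ret$exon_index), unique(non$exon_index))) {
    expect_equal(ret$n_windows[ret$exon_index == i][1] +
                   non$n_windows[non$exon_index == i][1],
                 all_prof$n_windows[all_prof$exon_index == i][1])
  }
  # slabs sit over retained first introns: intronic signal downstream of
  # exon 1 is higher in the retained class than the non-retained class
  r1 <- ret %>% filter(exon_index == 1, region == "intron")
  n1 <- non %>% filter(exon_index == 1, region == "intron")
  expect_gt(mean(r1$density), 2 * mean(n1$density))

  # uniform track -> all ordinal profiles constant and equal
  flat <- empty_track(gm$models$chrom_sizes)
  for (cm in names(flat$values)) flat$values[[cm]][] <- 5
  fp <- suppressWarnings(
    profiles_by_intron_index(flat, gm$models, calls, indices = 1:2,
                             retained = TRUE, library_size = 1e6))
  expect_equal(unique(fp$density), 5)
})
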