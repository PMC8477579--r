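# Seeded synthetic-data generator: gene models with short retained first
# introns in lncRNA genes, tag libraries with exonic nucleosome
# enrichment and H3K4me3 slab domains, and RNA-seq coverage with
# designated retained introns, plus a truth table tying it all together.

#' Simulation specification
#'
#' Bundles every generator parameter with its default study conditions.
#' A set of "surveyed" lncRNA genes each contribute one intron block
#' (upstream exon - intron - downstream exon); the joint slab/retention
#' label of each block is drawn from `ir_joint`, first-intron membership
#' from the label-conditional probabilities, and the surveyed intron's
#' length from the retained (short, median 192 bp) or non-retained
#' (median 2181 bp) log-normal. Defaults echo the magnitudes of the
#' organismal analysis the generator emulates: joint proportions
#' 57:10:52:81 over 200 regions, 67%/26% first-intron frequency by IR
#' class, a 1.28-fold exonic nucleosome enrichment, and >= 1 kb slabs.
#'
#' @param n_chroms,chrom_length Genome geometry (bp per chromosome).
#' @param n_lncrna,n_mrna Gene counts per biotype.
#' @param n_surveyed Number of lncRNA genes contributing a surveyed
#'   intron block (<= n_lncrna).
#' @param exon_count_range Min/max exons per transcript (>= 3 so every
#'   gene has internal exons and a non-first intron).
#' @param exon_length_range Min/max exon length (bp); the default
#'   140-160 bp matches the mononucleosome scale of internal exons.
#' @param retained_intron_meanlog,retained_intron_sdlog Log-normal
#'   parameters of retained (short) intron lengths; default median 192 bp.
#' @param lnc_intron_meanlog,lnc_intron_sdlog Non-retained lncRNA intron
#'   lengths; default median 2181 bp.
#' @param mrna_intron_meanlog,mrna_intron_sdlog mRNA intron lengths;
#'   default median 6000 bp.
#' @param ir_joint Probabilities of the four joint (M, IR) states of a
#'   surveyed block, in order M+IR+, M+IR-, M-IR+, M-IR-.
#' @param p_first_given_ir,p_first_given_noir Probability that the
#'   surveyed intron is the first intron, by IR state.
#' @param exon_enrichment_factor Relative nucleosome density on exons
#'   (>= 1).
#' @param slab_signal_level Relative tag density over slab intervals.
#' @param slab_extension Slab half-extension beyond the surveyed intron
#'   (bp each side), sized so every slab comfortably exceeds 1 kb.
#' @param n_tags Tags per simulated library.
#' @param rna_exon_depth_range Per-gene exonic RNA depth (uniform draw).
#' @param rna_intron_depth_frac Retained-intron depth as a fraction of
#'   the gene's exonic depth.
#' @param min_intergenic Minimum gap between adjacent genes (bp).
#' @param seed Integer seed; every generator stage derives its stream
#'   from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_chroms = 2, chrom_length = 3e6,
                     n_lncrna = 200, n_mrna = 50, n_surveyed = 200,
                     exon_count_range = c(3, 6),
                     exon_length_range = c(140, 160),
                     retained_intron_meanlog = log(192), retained_intron_sdlog = 0.35,
                     lnc_intron_meanlog = log(2181), lnc_intron_sdlog = 0.6,
                     mrna_intron_meanlog = log(6000), mrna_intron_sdlog = 0.8,
                     ir_joint = c(57, 10, 52, 81) / 200,
                     p_first_given_ir = 73 / 109, p_first_given_noir = 24 / 91,
                     exon_enrichment_factor = 1.28,
                     slab_signal_level = 20, slab_extension = 900,
                     n_tags = 1e5,
                     rna_exon_depth_range = c(10, 50),
                     rna_intron_depth_frac = 0.3,
                     min_intergenic = 2000,
                     seed = 1) {
  spec <- as.list(environment())
  if (n_surveyed > n_lncrna) abort("n_surveyed cannot exceed n_lncrna")
  if (exon_count_range[1] < 3) abort("exon_count_range must start at >= 3")
  if (exon_enrichment_factor < 1) abort("exon_enrichment_factor must be >= 1")
  if (abs(sum(ir_joint) - 1) > 1e-8) abort("ir_joint must sum to 1")
  structure(spec, class = "sim_spec")
}

rlnorm_clamped <- function(n, meanlog, sdlog, lo, hi) {
  pmin(hi, pmax(lo, round(rlnorm(n, meanlog, sdlog))))
}

# sample() treats a scalar first argument as 1:x; this keeps set semantics
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate gene models and the truth table
#'
#' Lays out non-overlapping multi-exonic genes along the simulated
#' chromosomes. Surveyed lncRNA genes get their joint (M, IR) label,
#' first/non-first surveyed intron, and label-conditional intron length
#' assigned here and recorded in the truth table, which the tag and RNA
#' generators then honour. Deterministic given the spec (including its
#' seed).
#'
#' @param spec A [sim_spec()].
#' @return List with `models` (a `gene_models`) and `truth` (one row per
#'   gene: labels, surveyed intron and block coordinates, slab interval
#'   for M-positive genes).
#' @export
simulate_gene_models <- function(spec) {
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  chrom_sizes <- setNames(rep(spec$chrom_length, spec$n_chroms), chroms)

  n_genes <- spec$n_lncrna + spec$n_mrna
  biotype <- c(rep("lncRNA", spec$n_lncrna), rep("mRNA", spec$n_mrna))
  surveyed <- c(seq_len(spec$n_lncrna) <= spec$n_surveyed, rep(FALSE, spec$n_mrna))
  # interleave biotypes along the genome so neither clusters on one chrom
  ord <- sample.int(n_genes)
  biotype <- biotype[ord]; surveyed <- surveyed[ord]

  joint_levels <- c("mp_irp", "mp_ira", "ma_irp", "ma_ira")
  exons_out <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  cursor <- 1000; ci <- 1L
  lnc_i <- 0L
  for (g in seq_len(n_genes)) {
    bt <- biotype[g]
    n_ex <- sample_one(seq(spec$exon_count_range[1], spec$exon_count_range[2]))
    ex_len <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]),
                     n_ex, replace = TRUE)
    n_in <- n_ex - 1L
    if (bt == "mRNA") {
      in_len <- rlnorm_clamped(n_in, spec$mrna_intron_meanlog, spec$mrna_intron_sdlog,
                               500, 30000)
    } else {
      in_len <- rlnorm_clamped(n_in, spec$lnc_intron_meanlog, spec$lnc_intron_sdlog,
                               500, 20000)
    }
    m_truth <- NA; ir_truth <- NA
    surv_idx <- NA_integer_
    if (surveyed[g]) {
      joint <- joint_levels[sample.int(4, 1, prob = spec$ir_joint)]
      m_truth <- joint %in% c("mp_irp", "mp_ira")
      ir_truth <- joint %in% c("mp_irp", "ma_irp")
      p_first <- if (ir_truth) spec$p_first_given_ir else spec$p_first_given_noir
      is_first <- runif(1) < p_first
      surv_idx <- if (is_first || n_in == 1L) 1L else sample_one(seq(2L, n_in))
      surv_len <- if (ir_truth) {
        rlnorm_clamped(1, spec$retained_intron_meanlog, spec$retained_intron_sdlog, 60, 20000)
      } else {
        rlnorm_clamped(1, spec$lnc_intron_meanlog, spec$lnc_intron_sdlog, 500, 20000)
      }
      in_len[surv_idx] <- surv_len
    }
    strand <- sample(c("+", "-"), 1)
    span <- sum(ex_len) + sum(in_len)
    gap <- round(runif(1, spec$min_intergenic, spec$min_intergenic + 3000))
    if (cursor + gap + span > spec$chrom_length - 1000) {
      ci <- ci + 1L
      if (ci > spec$n_chroms) {
        abort("genes do not fit on the simulated genome; increase chrom_length or n_chroms")
      }
      cursor <- 1000
    }
    gene_start <- cursor + gap
    gene_end <- gene_start + span
    cursor <- gene_end

    # transcription-direction offsets of exons within the gene
    piece_len <- numeric(2 * n_ex - 1)
    piece_len[seq(1, 2 * n_ex - 1, by = 2)] <- ex_len
    if (n_in > 0) piece_len[seq(2, 2 * n_ex - 2, by = 2)] <- in_len
    ends <- cumsum(piece_len)
    starts <- ends - piece_len
    exo <- seq(1, 2 * n_ex - 1, by = 2)
    t_start <- starts[exo]; t_end <- ends[exo]
    if (strand == "+") {
      g_start <- gene_start + t_start; g_end <- gene_start + t_end
    } else {
      g_start <- gene_end - t_end; g_end <- gene_end - t_start
    }
    gid <- sprintf("G%04d", g); tid <- sprintf("T%04d", g)
    exons_out[[g]] <- tibble(
      chrom = chroms[ci], start = as.integer(g_start), end = as.integer(g_end),
      strand = strand, gene_id = gid, transcript_id = tid,
      biotype = bt, n_exons = n_ex, exon_index = seq_len(n_ex)
    )
    # surveyed intron and block coordinates (genomic)
    in_t_start <- ends[exo][-n_ex]          # intron k starts where exon k ends
    in_t_end <- starts[exo][-1]
    if (!is.na(surv_idx)) {
      its <- in_t_start[surv_idx]; ite <- in_t_end[surv_idx]
      bts_ <- t_start[surv_idx]; bte_ <- t_end[surv_idx + 1L]
      if (strand == "+") {
        i_s <- gene_start + its; i_e <- gene_start + ite
        r_s <- gene_start + bts_; r_e <- gene_start + bte_
      } else {
        i_s <- gene_end - ite; i_e <- gene_end - its
        r_s <- gene_end - bte_; r_e <- gene_end - bts_
      }
    } else {
      i_s <- NA_real_; i_e <- NA_real_; r_s <- NA_real_; r_e <- NA_real_
    }
    slab_s <- if (isTRUE(m_truth)) max(0, i_s - spec$slab_extension) else NA_real_
    slab_e <- if (isTRUE(m_truth)) min(spec$chrom_length, i_e + spec$slab_extension) else NA_real_
    truth[[g]] <- tibble(
      gene_id = gid, transcript_id = tid, biotype = bt,
      chrom = chroms[ci], strand = strand,
      gene_start = gene_start, gene_end = gene_end, n_exons = n_ex,
      surveyed = surveyed[g], m_truth = m_truth, ir_truth = ir_truth,
      surveyed_intron_index = surv_idx,
      intron_start = i_s, intron_end = i_e,
      intron_length = i_e - i_s,
      region_start = r_s, region_end = r_e,
      slab_start = slab_s, slab_end = slab_e
    )
  }
  exons <- bind_rows(exons_out) %>% arrange(.data$chrom, .data$start, .data$transcript_id)
  models <- structure(list(exons = exons, chrom_sizes = chrom_sizes),
                      class = "gene_models")
  list(models = models, truth = bind_rows(truth))
}

#' Simulate a sequencing-tag library
#'
#' Draws `n_tags` tag records whose 150 bp 3'-extended footprints
#' realise a programmed coverage contrast: a uniform background over the
#' genome, an `exon_enrichment_factor`-fold density over exons, and (for
#' the histone-mark library) `slab_signal_level`-fold density over the
#' slab intervals of M-positive surveyed genes. Background and slab tags
#' have their footprints centred on positions sampled uniformly within
#' the component; the exonic excess is modelled as nucleosome-positioned
#' footprints centred on each exon, so the exon/intron density step is
#' realised sharply in coverage rather than blurred over the footprint
#' half-width. Tags are 25 bp reads placed at the footprint's 5' end on
#' a random strand, so the standard 150 bp 3' extension reconstructs the
#' footprint exactly.
#'
#' @param models,truth Output of [simulate_gene_models()].
#' @param spec The [sim_spec()].
#' @param mark `"nucleosome"` (total library, no slabs) or `"H3K4me3"`
#'   (slab intervals overlaid).
#' @return A `tag_library`.
#' @export
simulate_nucleosome_tags <- function(models, truth, spec,
                                     mark = c("nucleosome", "H3K4me3")) {
  mark <- match.arg(mark)
  set.seed(spec$seed + if (mark == "nucleosome") 101L else 202L)
  chrom_sizes <- models$chrom_sizes
  genome_bp <- sum(chrom_sizes)
  ex <- models$exons
  f <- spec$exon_enrichment_factor
  slabs <- if (mark == "H3K4me3") {
    filter(truth, !is.na(.data$m_truth) & .data$m_truth)
  } else truth[0, ]

  # component weights: expected tags proportional to added coverage mass
  w_bg <- genome_bp
  w_ex <- rep((f - 1) * 150, nrow(ex))        # positioned footprints stack per exon
  w_sl <- if (nrow(slabs) > 0) (spec$slab_signal_level - 1) * (slabs$slab_end - slabs$slab_start) else numeric(0)
  w <- c(w_bg, w_ex, w_sl)
  counts <- as.vector(rmultinom(1, spec$n_tags, w / sum(w)))
  n_bg <- counts[1]
  n_ex <- counts[seq_along(w_ex) + 1L]
  n_sl <- if (length(w_sl) > 0) counts[length(w_ex) + 1L + seq_along(w_sl)] else integer(0)

  # background: centres uniform over the genome (clear of chromosome ends)
  bg_chrom <- sample(names(chrom_sizes), n_bg, replace = TRUE,
                     prob = chrom_sizes / genome_bp)
  bg_center <- floor(runif(n_bg, 75, chrom_sizes[bg_chrom] - 75))
  centers <- tibble(chrom = bg_chrom, center = bg_center)
  # exon excess: footprints centred on the exon midpoint
  if (sum(n_ex) > 0) {
    ei <- rep(seq_len(nrow(ex)), n_ex)
    centers <- bind_rows(centers, tibble(
      chrom = ex$chrom[ei],
      center = floor((ex$start[ei] + ex$end[ei]) / 2)
    ))
  }
  # slab excess: centres uniform within the slab interval
  if (sum(n_sl) > 0) {
    si <- rep(seq_len(nrow(slabs)), n_sl)
    centers <- bind_rows(centers, tibble(
      chrom = slabs$chrom[si],
      center = floor(runif(sum(n_sl), slabs$slab_start[si], slabs$slab_end[si]))
    ))
  }
  n <- nrow(centers)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # footprint [c - 75, c + 75); the 25 bp read sits at the 5' end
  start <- ifelse(strand == "+", centers$center - 75, centers$center + 50)
  start <- pmax(0, pmin(start, chrom_sizes[centers$chrom] - 25))
  tags <- tibble(chrom = centers$chrom, start = as.integer(start),
                 end = as.integer(start + 25L), strand = strand) %>%
    arrange(.data$chrom, .data$start)
  structure(list(tags = tags, total_tags = nrow(tags),
                 source = sprintf("simulated:%s", mark)),
            class = "tag_library")
}

#' Simulate RNA-seq coverage
#'
#' Builds a coverage track in which every gene has a constant exonic
#' depth (drawn per gene) and introns carry depth
#' `rna_intron_depth_frac * exon depth` when their truth label is
#' retained and exactly zero otherwise, so truth recovery by the
#' classifier is exact. `poisson = TRUE` replaces each base by a Poisson
#' draw around that mean and `noise_rate` adds low-rate spurious
#' coverage everywhere, for robustness tests.
#'
#' @inheritParams simulate_nucleosome_tags
#' @param poisson Sample per-base Poisson noise around the programmed mean.
#' @param noise_rate Mean of spurious background coverage added to every
#'   base (0 = none).
#' @return List with `track` (a `coverage_track`) and `truth` (input
#'   truth with an `rna_exon_depth` column).
#' @export
simulate_rnaseq_coverage <- function(models, truth, spec,
                                     poisson = FALSE, noise_rate = 0) {
  set.seed(spec$seed + 303L)
  ex <- models$exons
  depth <- runif(nrow(truth), spec$rna_exon_depth_range[1], spec$rna_exon_depth_range[2])
  truth <- mutate(truth, rna_exon_depth = depth)
  track <- empty_track(models$chrom_sizes)
  ex_depth <- depth[match(ex$gene_id, truth$gene_id)]
  track <- add_intervals(track, ex$chrom, ex$start, ex$end, ex_depth)
  ret <- filter(truth, !is.na(.data$ir_truth) & .data$ir_truth)
  if (nrow(ret) > 0) {
    track <- add_intervals(track, ret$chrom, ret$intron_start, ret$intron_end,
                           spec$rna_intron_depth_frac * ret$rna_exon_depth)
  }
  if (poisson || noise_rate > 0) {
    for (cm in names(track$values)) {
      mu <- track$values[[cm]] + noise_rate
      track$values[[cm]] <- if (poisson) as.numeric(rpois(length(mu), mu)) else mu
    }
  }
  list(track = track, truth = truth)
}

#' Generate a complete on-disk fixture
#'
#' Runs the three generator stages and writes mutually consistent files:
#' `models.gtf`, `chrom.sizes`, `nucleosome_tags.bed` (total library),
#' `h3k4me3.bedGraph` (histone-mark coverage built from its simulated
#' tag library), `rna.bedGraph`, `truth.tsv`, `regions.bed` (surveyed
#' blocks) and a `manifest.json` echoing the spec and seed.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the in-memory objects (`models`,
#'   `truth`, tag libraries, tracks) and file `paths`.
#' @export
simulate_dataset <- function(spec, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("output directory %s exists and is non-empty (use force = TRUE)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulate_gene_models(spec)
  nuc <- simulate_nucleosome_tags(gm$models, gm$truth, spec, mark = "nucleosome")
  h3k <- simulate_nucleosome_tags(gm$models, gm$truth, spec, mark = "H3K4me3")
  rna <- simulate_rnaseq_coverage(gm$models, gm$truth, spec)
  h3k_track <- build_coverage(h3k, gm$models$chrom_sizes, extension = 150)

  paths <- list(
    gtf = file.path(dir, "models.gtf"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    nucleosome_tags = file.path(dir, "nucleosome_tags.bed"),
    h3k4me3 = file.path(dir, "h3k4me3.bedGraph"),
    rna = file.path(dir, "rna.bedGraph"),
    truth = file.path(dir, "truth.tsv"),
    regions = file.path(dir, "regions.bed"),
    manifest = file.path(dir, "manifest.json")
  )
  write_gtf(gm$models, paths$gtf)
  write_chrom_sizes(gm$models$chrom_sizes, paths$chrom_sizes)
  readr::write_tsv(tibble(chrom = nuc$tags$chrom, start = nuc$tags$start,
                          end = nuc$tags$end, name = "tag", score = 0,
                          strand = nuc$tags$strand),
                   paths$nucleosome_tags, col_names = FALSE)
  write_track(h3k_track, paths$h3k4me3, dialect = "bedGraph")
  write_track(rna$track, paths$rna, dialect = "bedGraph")
  readr::write_tsv(rna$truth, paths$truth)
  surveyed <- filter(rna$truth, .data$surveyed)
  write_bed(tibble(chrom = surveyed$chrom, start = surveyed$region_start,
                   end = surveyed$region_end, name = surveyed$gene_id),
            paths$regions)
  spec_echo <- unclass(spec)
  spec_echo <- spec_echo[!vapply(spec_echo, is.function, logical(1))]
  jsonlite::write_json(list(generator = "slabir", seed = spec$seed, spec = spec_echo),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(models = gm$models, truth = rna$truth, nucleosome = nuc,
                 h3k4me3 = h3k, h3k4me3_track = h3k_track, rna = rna$track,
                 paths = paths))
}

#' Draw joint slab/retention labels for surveyed regions
#'
#' The label-assignment stage of the generator in isolation: draws n
#' joint (M, IR) states from a four-state probability vector. Useful for
#' studying the association test's behaviour over many replicates
#' without re-simulating tracks.
#'
#' @param n Number of regions.
#' @param joint Probabilities (M+IR+, M+IR-, M-IR+, M-IR-).
#' @param seed Optional seed.
#' @return Tibble with logical columns `m` and `ir`.
#' @export
simulate_mir_labels <- function(n, joint = c(57, 10, 52, 81) / 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(4, n, replace = TRUE, prob = joint)
  tibble(m = k %in% c(1L, 2L), ir = k %in% c(1L, 3L))
}
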