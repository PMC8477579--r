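# The slab x IR association: 2x2 contingency table, uncorrected Pearson
# chi-squared test, concordance, and per-class intron summaries.

#' Pearson chi-squared test for a 2x2 table
#'
#' Computes the uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' expectations from the row/column margins and the upper-tail p-value on
#' 1 degree of freedom. No Yates continuity correction is applied: the
#' statistic is the plain Pearson chi-squared, which for a 2x2 table
#' equals the closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param cells Four non-negative counts in row-major order
#'   (a = row1/col1, b = row1/col2, c = row2/col1, d = row2/col2).
#' @return List with `statistic`, `p_value` and `df` (= 1).
#' @export
pearson_chi2 <- function(cells) {
  if (length(cells) != 4 || any(cells < 0)) abort("`cells` must be four non-negative counts")
  o <- matrix(as.numeric(cells), nrow = 2, byrow = TRUE)
  rs <- rowSums(o); cs <- colSums(o); n <- sum(o)
  if (any(rs == 0) || any(cs == 0)) abort("zero row/column margin: chi-squared test undefined")
  e <- outer(rs, cs) / n
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Slab x intron-retention contingency analysis
#'
#' Cross-tabulates slab presence (M) against intron retention (IR) over a
#' set of surveyed regions and tests independence with the uncorrected
#' Pearson chi-squared test ([pearson_chi2()]). Concordance is the
#' fraction of regions where the two flags agree
#' (`(M&IR + !M&!IR) / n`).
#'
#' @param m_flags Logical vector: slab present per region.
#' @param ir_flags Logical vector: intron retained per region (same
#'   length and order).
#' @return A `slab_ir_test` object with the 2x2 table (rows M
#'   present/absent, columns IR present/absent), statistic, p-value,
#'   concordance and n. [tidy()] returns the cells; [glance()] the test
#'   summary.
#' @export
slab_ir_test <- function(m_flags, ir_flags) {
  if (length(m_flags) != length(ir_flags)) abort("flag vectors differ in length")
  if (length(m_flags) == 0) abort("empty flag vectors")
  if (anyNA(m_flags) || anyNA(ir_flags)) abort("flags must not contain NA")
  cells <- c(sum(m_flags & ir_flags), sum(m_flags & !ir_flags),
             sum(!m_flags & ir_flags), sum(!m_flags & !ir_flags))
  slab_ir_test_from_cells(cells)
}

#' @rdname slab_ir_test
#' @param cells Four counts (M+IR+, M+IR-, M-IR+, M-IR-), for reproducing
#'   a printed table without the underlying tracks.
#' @export
slab_ir_test_from_cells <- function(cells) {
  tab <- matrix(as.numeric(cells), nrow = 2, byrow = TRUE,
                dimnames = list(M = c("M present", "M absent"),
                                IR = c("IR present", "IR absent")))
  test <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("zero row/column margin: chi-squared statistic undefined, reported as NA")
    list(statistic = NA_real_, p_value = NA_real_, df = 1L)
  } else {
    pearson_chi2(cells)
  }
  structure(list(
    table = tab,
    statistic = test$statistic,
    p_value = test$p_value,
    df = test$df,
    concordance = (tab[1, 1] + tab[2, 2]) / sum(tab),
    n = sum(tab)
  ), class = "slab_ir_test")
}

#' @export
print.slab_ir_test <- function(x, ...) {
  cat("Slab (M) x intron retention (IR) association\n\n")
  print(x$table)
  cat(sprintf("\nPearson chi-squared (no continuity correction): X2 = %.2f, df = %d, p = %.0e\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("Concordance: %.1f%% of %d regions\n", 100 * x$concordance, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slab x IR test
#'
#' `tidy()` returns one row per cell of the 2x2 table; `glance()` a
#' one-row summary (statistic, p-value, concordance, n).
#'
#' @param x A `slab_ir_test`.
#' @param ... Unused.
#' @export
tidy.slab_ir_test <- function(x, ...) {
  tibble(
    m = rep(c(TRUE, FALSE), each = 2),
    ir = rep(c(TRUE, FALSE), 2),
    n = as.vector(t(x$table))
  )
}

#' @rdname tidy.slab_ir_test
#' @export
glance.slab_ir_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = x$df,
         concordance = x$concordance, n = x$n)
}

#' Per-IR-class intron length and first-intron summaries
#'
#' Summarises intron lengths and first-intron frequency within the
#' retained and non-retained classes: n, median and mean length, the
#' standard error of the mean (`sd / sqrt(n)`; 0 for a single intron),
#' the number of first introns and their fraction of the class.
#'
#' @param calls IR-call tibble (needs `retained`, `length`, `is_first`).
#' @return One row per IR class.
#' @export
group_length_stats <- function(calls) {
  if (nrow(calls) == 0) abort("no IR calls to summarise")
  present <- unique(calls$retained)
  if (length(present) < 2) {
    warn(sprintf("only one IR class present (retained = %s); the other summary is omitted",
                 present))
  }
  calls %>%
    group_by(.data$retained) %>%
    summarise(
      n = n(),
      median_length = median(.data$length),
      mean_length = mean(.data$length),
      se_length = if_else(n() > 1, sd(.data$length) / sqrt(n()), 0),
      n_first = sum(.data$is_first),
      first_fraction = .data$n_first / n(),
      .groups = "drop"
    ) %>%
    mutate(group = if_else(.data$retained, "IR present", "IR absent"),
           .before = 1) %>%
    arrange(desc(.data$retained))
}

#' First-intron frequency per IR class
#'
#' Fraction of each IR class made up of first introns.
#'
#' @inheritParams group_length_stats
#' @return Tibble with `retained`, `n`, `n_first`, `first_fraction`.
#' @export
first_intron_frequency <- function(calls) {
  group_length_stats(calls) %>%
    select("group", "retained", "n", "n_first", "first_fraction")
}
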