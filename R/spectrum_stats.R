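#' Construct an observed/expected category table
#'
#' @param categories Category labels.
#' @param observed Integer observed counts.
#' @param expected Real expected counts; must be positive and sum to the
#'   observed total (within 1e-9 relative tolerance).
#' @return An `ObservedExpected` data frame.
#' @export
observed_expected <- function(categories, observed, expected) {
  stopifnot(length(categories) == length(observed),
            length(observed) == length(expected))
  if (any(expected <= 0)) stop("expected counts must all be positive")
  if (abs(sum(observed) - sum(expected)) >
      1e-9 * max(1, sum(observed)))
    stop("observed and expected totals differ")
  structure(data.frame(category = as.character(categories),
                       observed = as.numeric(observed),
                       expected = as.numeric(expected),
                       stringsAsFactors = FALSE),
            class = c("ObservedExpected", "data.frame"))
}

test_result <- function(method, statistic, df, p_value, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 df = if (is.null(df)) NA_integer_ else unname(df),
                 p_value = unname(p_value), ...),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Bin mutations by genomic position
#'
#' Groups mutation positions into fixed-width windows starting at position 1
#' (1-2000, 2001-4000, ... by default) and computes expected counts for a
#' random-placement null. Expected counts are proportional to each bin's
#' overlap with the analyzed region (default: the coding region 577-16023),
#' or equal per bin with `expected = "equal"`. A trailing bin whose overlap
#' with the region is smaller than half the bin width is pooled with the
#' preceding bin by default, so that the chi-squared approximation is not
#' invalidated by a near-empty expected cell.
#'
#' @param ms A `MutationSet` (typically coding-region filtered).
#' @param bin_size Window width in bases (default 2000).
#' @param region Analyzed region `c(start, end)` used for expectations.
#' @param expected `"length"` (proportional to bin/region overlap) or
#'   `"equal"`.
#' @param merge_small Pool a small trailing bin into its neighbour.
#' @return An `ObservedExpected` table, with bin labels like `"1-2000"`.
#' @export
positional_bins <- function(ms, bin_size = 2000L, region = CODING_REGION,
                            expected = c("length", "equal"),
                            merge_small = TRUE) {
  expected <- match.arg(expected)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("bin_size must be >= 1")
  pos <- as.data.frame(ms)$position
  L <- GENOME_LENGTH
  starts <- seq.int(1L, L, by = bin_size)
  ends <- pmin(starts + bin_size - 1L, L)
  overlap <- pmax(0L, pmin(ends, region[2L]) - pmax(starts, region[1L]) + 1L)
  if (merge_small && length(starts) > 1L &&
      overlap[length(starts)] < bin_size / 2) {
    k <- length(starts)
    ends[k - 1L] <- ends[k]
    overlap[k - 1L] <- overlap[k - 1L] + overlap[k]
    starts <- starts[-k]; ends <- ends[-k]; overlap <- overlap[-k]
  }
  keep <- overlap > 0L
  starts <- starts[keep]; ends <- ends[keep]; overlap <- overlap[keep]
  if (any(pos < region[1L] | pos > region[2L]))
    stop("positions outside the analyzed region; apply filter_coding_region")
  obs <- tabulate(findInterval(pos, starts), nbins = length(starts))
  exp_counts <- if (expected == "length")
    length(pos) * overlap / sum(overlap)
  else rep(length(pos) / length(starts), length(starts))
  observed_expected(paste0(starts, "-", ends), obs, exp_counts)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson goodness-of-fit: X^2 = sum (O - E)^2 / E with
#' `df = categories - 1`, upper-tail p from the chi-squared distribution.
#' The statistic is computed directly so it can also be applied to
#' simulation matrices; it agrees with `chisq.test(x, p = ...)`.
#'
#' @param oe An `ObservedExpected` table.
#' @return A `TestResult`.
#' @examples
#' chisq_goodness_of_fit(observed_expected(c("a", "b"), c(10, 0), c(5, 5)))
#' @export
chisq_goodness_of_fit <- function(oe) {
  if (any(oe$expected <= 0)) stop("expected counts must all be positive")
  x2 <- sum((oe$observed - oe$expected)^2 / oe$expected)
  df <- nrow(oe) - 1L
  test_result("Chi-squared goodness-of-fit", x2, df,
              pchisq(x2, df, lower.tail = FALSE),
              observed = oe$observed, expected = oe$expected,
              categories = oe$category)
}

#' Gene-type goodness-of-fit against genome occupancy
#'
#' Tests whether mutations are distributed over gene types (protein, tRNA,
#' rRNA) in proportion to the fraction of the analyzed region occupied by
#' each type. Mutations falling in the few intergenic bases inside the
#' coding span are excluded from the test (their count is reported in the
#' result as `n_noncoding_excluded`).
#'
#' @param ms A coding-region-filtered `MutationSet`.
#' @param ann A `MitoAnnotation`.
#' @param region Analyzed region for the length expectations.
#' @return A `TestResult` with the observed/expected table attached.
#' @export
gene_type_gof <- function(ms, ann, region = CODING_REGION) {
  pos <- as.data.frame(ms)$position
  cls <- region_class(ann, pos)
  keep <- cls != "noncoding"
  lens <- gene_type_lengths(ann, region)[c("protein", "tRNA", "rRNA")]
  obs <- table(factor(cls[keep], levels = names(lens)))
  if (sum(obs) == 0L) stop("no mutations in annotated genes")
  oe <- observed_expected(names(lens), as.integer(obs),
                          sum(obs) * lens / sum(lens))
  res <- chisq_goodness_of_fit(oe)
  res$method <- "Gene-type goodness-of-fit"
  res$n_noncoding_excluded <- sum(!keep)
  res
}

#' Bonferroni-corrected significance thresholds
#'
#' The fixed-threshold representation of a Bonferroni correction over `k`
#' tests: stars at 0.05/k, 0.01/k and 0.001/k.
#'
#' @param k Number of tests.
#' @return Named numeric vector (`*`, `**`, `***`).
#' @export
bonferroni_thresholds <- function(k) {
  setNames(c(0.05, 0.01, 0.001) / k, c("*", "**", "***"))
}

star_label <- function(p, thresholds) {
  stars <- names(thresholds)[p < thresholds]
  if (length(stars)) stars[length(stars)] else ""
}

#' Cross-cohort contingency comparison
#'
#' Builds a categories-by-groups contingency table and runs Pearson
#' chi-squared tests (no continuity correction, including 2x2 tables):
#' one overall r-by-c test and one per pair of groups. Multiple testing over
#' the k pairwise tests is handled with Bonferroni fixed thresholds
#' (0.05/k, 0.01/k, 0.001/k; for k = 3 these are the printed 0.017, 0.003,
#' 0.0003); Bonferroni-inflated p-values are emitted alongside.
#'
#' @param groups Either a categories-by-groups count matrix, or a named list
#'   of `MutationSet`s combined with `categorizer`.
#' @param categorizer Function mapping a `MutationSet` to a vector of
#'   category labels (one per mutation); required for list input.
#' @param correct Apply the Yates continuity correction in 2x2 tables
#'   (default `FALSE`; available for sensitivity checks).
#' @return List with `table`, `overall` (`TestResult`), `pairwise`
#'   (data.frame: pair, statistic, df, p_value, p_bonferroni, stars) and
#'   `thresholds`.
#' @export
contingency_compare <- function(groups, categorizer = NULL, correct = FALSE) {
  if (is.matrix(groups) || is.table(groups)) {
    tab <- as.matrix(groups)
  } else {
    if (is.null(categorizer))
      stop("categorizer required when groups is a list of MutationSets")
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("groups must be named")
    cats <- lapply(groups, categorizer)
    lev <- sort(unique(unlist(cats)))
    tab <- vapply(cats, function(x) table(factor(x, levels = lev)),
                  numeric(length(lev)))
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1L,
                                         dimnames = list(lev, names(groups)))
  }
  if (ncol(tab) < 2L) stop("need at least two groups")
  if (any(colSums(tab) == 0)) stop("group with zero total: ",
                                   paste(colnames(tab)[colSums(tab) == 0],
                                         collapse = ", "))
  run <- function(m) {
    m <- m[rowSums(m) > 0, , drop = FALSE]
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    test_result("Pearson chi-squared contingency", ct$statistic,
                ct$parameter, ct$p.value)
  }
  overall <- run(tab)
  pairs <- utils::combn(ncol(tab), 2L)
  k <- ncol(pairs)
  thr <- bonferroni_thresholds(k)
  pw <- lapply(seq_len(k), function(j) {
    m <- tab[, pairs[, j], drop = FALSE]
    r <- run(m)
    data.frame(pair = paste(colnames(m), collapse = " vs "),
               statistic = r$statistic, df = r$df, p_value = r$p_value,
               p_bonferroni = min(1, r$p_value * k),
               stars = star_label(r$p_value, thr),
               stringsAsFactors = FALSE)
  })
  list(table = tab, overall = overall, pairwise = do.call(rbind, pw),
       thresholds = thr)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two score samples. In `auto` mode the exact null distribution is
#' used when both samples have at most 12 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used. `exact` and `normal_approx` force the respective
#' computation.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return A `TestResult` with the Mann-Whitney `W` statistic.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = length(x) <= 12L && length(y) <= 12L && !ties,
                  exact = TRUE,
                  normal_approx = FALSE)
  if (exact && ties) exact <- FALSE  # exact null undefined with ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = !exact))
  test_result(
    if (exact) "Wilcoxon rank-sum (exact)"
    else "Wilcoxon rank-sum (normal approximation)",
    wt$statistic, NULL, wt$p.value,
    n_x = length(x), n_y = length(y))
}
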