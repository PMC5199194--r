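#' Mean and standard error of a metric
#'
#' @param values numeric vector; NAs are dropped (excluded cells).
#' @return list with \code{n}, \code{mean}, \code{sem} (sample SD / sqrt(n);
#'   NA when n < 2).
#' @export
mean_sem <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0L) abort("no non-missing values to summarize")
  list(n = n, mean = mean(x),
       sem = if (n < 2L) NA_real_ else stats::sd(x) / sqrt(n))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided, asymptotic p-value (the convention used throughout the
#' cohort comparisons).
#'
#' @param a,b numeric samples.
#' @return list with \code{statistic} (D), \code{p}, \code{n} (c(n_a, n_b)).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       n = c(length(a), length(b)))
}

#' One-sample K-S test against Uniform(0, 90)
#'
#' Tests a sample of inter-ocular orientation differences against the
#' random-matching null: if preferred orientations through the two eyes are
#' independent and uniform, their circular difference is Uniform(0, 90)
#' with mean 45 degrees.
#'
#' @param deltas orientation differences in degrees, all in [0, 90].
#' @return list with \code{statistic} (D), \code{p}, \code{n}.
#' @export
ks_vs_uniform <- function(deltas) {
  if (length(deltas) == 0L) abort("empty sample")
  if (any(deltas < 0 | deltas > 90, na.rm = TRUE))
    abort("delta values must lie in [0, 90]")
  x <- deltas[!is.na(deltas)]
  kt <- suppressWarnings(stats::ks.test(x, stats::punif, 0, 90, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value, n = length(x))
}

#' Paired t-test
#'
#' Two-sided paired t-test on the element-wise differences. When every
#' difference is exactly zero the statistic is reported as 0 with an NA
#' p-value and a \code{degenerate} flag.
#'
#' @param a,b paired numeric samples of equal length; pairs with any NA are
#'   dropped.
#' @return list with \code{statistic} (t), \code{p}, \code{df}, \code{n},
#'   \code{degenerate}.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples differ in length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) abort("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(statistic = 0, p = NA_real_, df = n - 1L, n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = n, degenerate = FALSE)
}

#' Pearson correlation
#'
#' Pearson's r with the two-sided p-value from the t transform.
#'
#' @param a,b paired numeric samples; pairs with any NA are dropped.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples differ in length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) abort("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort("zero variance in a sample; correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

# pull one per-cell metric out of a list of cell_result objects
metric_vector <- function(results, field, element = NULL) {
  vapply(results, function(r) {
    v <- r[[field]]
    if (!is.null(element)) v <- v[[element]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
}

#' Cohort comparison battery
#'
#' Aggregates two cohorts of voltage-clamp \code{cell_result}s (typically
#' young vs adult) into per-metric summaries (n, mean, SEM) and the
#' standard test battery: two-sample K-S between cohorts on the total and
#' thalamic \eqn{\Delta O}; one-sample K-S of each \eqn{\Delta O} sample
#' against Uniform(0, 90); paired t between total and thalamic
#' \eqn{\Delta O} within each cohort; paired t between the contralateral and
#' ipsilateral thalamic-cortical differences within each cohort; and the
#' Pearson correlation between thalamic and total \eqn{\Delta O} per
#' cohort. Cells with undefined preferences are excluded listwise per
#' statistic, with exclusion counts in the QC slot.
#'
#' @param young,adult lists of \code{cell_result} objects.
#' @param labels length-2 character, cohort labels.
#' @return object of class \code{cohort_comparison}.
#' @export
compare_cohorts <- function(young, adult, labels = c("young", "adult")) {
  if (length(young) == 0L || length(adult) == 0L) abort("empty cohort")
  groups <- list(young, adult)
  names(groups) <- labels

  metrics <- list(
    dO_total = function(r) r$dO[["total"]],
    dO_thalamic = function(r) r$dO[["thalamic"]],
    dO_cortical = function(r) r$dO[["cortical"]],
    thal_total_diff_contra = function(r) r$thal_total_diff[["contra"]],
    thal_total_diff_ipsi = function(r) r$thal_total_diff[["ipsi"]],
    thal_cort_diff_contra = function(r) r$thal_cort_diff[["contra"]],
    thal_cort_diff_ipsi = function(r) r$thal_cort_diff[["ipsi"]],
    scale_contra = function(r) r$scale_factor[["contra"]],
    scale_ipsi = function(r) r$scale_factor[["ipsi"]],
    ci_ratio_total = function(r) r$ci_ratio_total,
    ci_ratio_thalamic = function(r) r$ci_ratio_thalamic)

  pull <- function(results, fn) vapply(results, function(r) {
    v <- tryCatch(fn(r), error = function(e) NA_real_)
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)

  summaries <- lapply(groups, function(g) {
    out <- list()
    for (m in names(metrics)) {
      x <- pull(g, metrics[[m]])
      out[[m]] <- if (all(is.na(x))) list(n = 0L, mean = NA_real_, sem = NA_real_)
                  else mean_sem(x)
    }
    out
  })

  tests <- list()
  excluded <- list()
  add_test <- function(name, grp, res) {
    tests[[length(tests) + 1]] <<- c(list(name = name, groups = grp), res)
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)

  for (m in c("dO_total", "dO_thalamic")) {
    xs <- lapply(groups, function(g) {
      v <- pull(g, metrics[[m]]); v[!is.na(v)]
    })
    excluded[[m]] <- vapply(groups, function(g)
      sum(is.na(pull(g, metrics[[m]]))), 0L)
    r <- safe(ks_two_sample(xs[[1]], xs[[2]]))
    if (!is.null(r)) add_test("ks_two_sample", paste(labels, collapse = " vs "),
                              c(metric = m, r))
    for (i in seq_along(groups)) {
      ru <- safe(ks_vs_uniform(xs[[i]]))
      if (!is.null(ru)) add_test("ks_vs_uniform", labels[i], c(metric = m, ru))
    }
  }
  for (i in seq_along(groups)) {
    tot <- pull(groups[[i]], metrics$dO_total)
    tha <- pull(groups[[i]], metrics$dO_thalamic)
    r <- safe(paired_t(tot, tha))
    if (!is.null(r)) add_test("paired_t", labels[i],
                              c(metric = "dO_total_vs_dO_thalamic", r))
    tcc <- pull(groups[[i]], metrics$thal_cort_diff_contra)
    tci <- pull(groups[[i]], metrics$thal_cort_diff_ipsi)
    r <- safe(paired_t(tci, tcc))
    if (!is.null(r)) add_test("paired_t", labels[i],
                              c(metric = "thal_cort_diff_ipsi_vs_contra", r))
    r <- safe(pearson_cor(tha, tot))
    if (!is.null(r)) add_test("pearson", labels[i],
                              c(metric = "dO_thalamic_vs_dO_total", r))
  }

  structure(list(labels = labels, summaries = summaries, tests = tests,
                 excluded = excluded),
            class = "cohort_comparison")
}

# plain-list view used for cohort_summary.json
cohort_summary_list <- function(x) {
  stopifnot(inherits(x, "cohort_comparison"))
  list(groups = x$summaries, tests = x$tests,
       excluded_cells = x$excluded)
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison:", paste(x$labels, collapse = " vs "), "\n\n")
  for (g in names(x$summaries)) {
    cat(sprintf("%s (mean +/- SEM):\n", g))
    s <- x$summaries[[g]]
    for (m in names(s)) {
      if (s[[m]]$n == 0L) next
      cat(sprintf("  %-24s %6.2f +/- %-5.2f (n=%d)\n", m,
                  s[[m]]$mean, s[[m]]$sem %||% NA, s[[m]]$n))
    }
  }
  cat("\nTests:\n")
  for (tst in x$tests) {
    stat <- tst$statistic %||% tst$r
    cat(sprintf("  %-14s %-16s %-28s stat=%6.3f p=%s\n",
                tst$name, tst$groups, tst$metric, stat,
                format.pval(tst$p %||% NA_real_, digits = 3)))
  }
  invisible(x)
}
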