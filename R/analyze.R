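#' Analyze every cell of a dataset
#'
#' Runs \code{\link{assemble_cell}} on each cell and collects the per-cell
#' results, a long tuning-curve table and a QC report (cells dropped with
#' reasons, clipped-direction fractions, adaptation flags).
#'
#' @param dataset a \code{\link{bm_dataset}}.
#' @param groups optional named character vector mapping cell_id to a
#'   cohort label (stored in the results table).
#' @param config a \code{\link{bm_config}}.
#' @return object of class \code{bm_analysis} with elements \code{cells}
#'   (list of \code{cell_result}), \code{curves} (data frame), \code{qc},
#'   \code{config}, \code{protocol}.
#' @export
analyze_dataset <- function(dataset, groups = NULL, config = bm_config()) {
  validate_dataset(dataset)
  results <- list()
  failed <- list()
  for (cid in names(dataset$cells)) {
    r <- tryCatch(assemble_cell(dataset$cells[[cid]], dataset$protocol, config),
                  error = function(e) e)
    if (inherits(r, "error")) failed[[cid]] <- conditionMessage(r)
    else results[[cid]] <- r
  }
  if (length(results) == 0L)
    abort("no cell could be analyzed (%d failed)", length(failed))

  rows <- list()
  for (r in results) {
    for (key in names(r$curves)) {
      cv <- r$curves[[key]]
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = r$cell_id, eye = cv$eye, input_type = cv$input_type,
        direction_deg = cv$directions, magnitude = cv$magnitudes,
        units = cv$units,
        n_cycles_used = if (is.null(cv$n_cycles_used)) NA_integer_
                        else cv$n_cycles_used,
        stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, rows)

  structure(list(
    cells = results, curves = curves,
    groups = groups,
    qc = list(failed_cells = failed,
              undefined_pref = lapply(results, function(r) r$qc$undefined_pref),
              adapted_directions = vapply(results, function(r)
                r$qc$adapted_directions, 0L)),
    config = config, protocol = dataset$protocol),
    class = "bm_analysis")
}

#' Per-cell metrics table
#'
#' One row per cell: preferred orientation and gOSI for every
#' (eye x input type) combination, the three inter-ocular differences, the
#' thalamic-total and thalamic-cortical differences per eye, scale factors,
#' contra/ipsi ratios and QC flags.
#'
#' @param analysis a \code{bm_analysis}.
#' @return data frame.
#' @export
cell_results_table <- function(analysis) {
  stopifnot(inherits(analysis, "bm_analysis"))
  combos <- c("contra.total", "contra.thalamic", "contra.cortical",
              "ipsi.total", "ipsi.thalamic", "ipsi.cortical")
  rows <- lapply(analysis$cells, function(r) {
    g <- if (!is.null(analysis$groups)) analysis$groups[[r$cell_id]] %||% NA_character_
         else NA_character_
    row <- data.frame(cell_id = r$cell_id, age_group = g,
                      clamp_mode = r$clamp_mode, stringsAsFactors = FALSE)
    for (cmb in combos) {
      row[[paste0("pref_O_", sub("\\.", "_", cmb))]] <-
        if (cmb %in% names(r$pref_O)) r$pref_O[[cmb]] else NA_real_
      row[[paste0("gOSI_", sub("\\.", "_", cmb))]] <-
        if (cmb %in% names(r$gOSI)) r$gOSI[[cmb]] else NA_real_
    }
    row$dO_total <- r$dO[["total"]]
    row$dO_thalamic <- r$dO[["thalamic"]]
    row$dO_cortical <- r$dO[["cortical"]]
    row$thal_total_diff_contra <- r$thal_total_diff[["contra"]]
    row$thal_total_diff_ipsi <- r$thal_total_diff[["ipsi"]]
    row$thal_cort_diff_contra <- r$thal_cort_diff[["contra"]]
    row$thal_cort_diff_ipsi <- r$thal_cort_diff[["ipsi"]]
    row$scale_contra <- r$scale_factor[["contra"]]
    row$scale_ipsi <- r$scale_factor[["ipsi"]]
    row$ci_ratio_total <- r$ci_ratio_total
    row$ci_ratio_thalamic <- r$ci_ratio_thalamic
    row$n_spikes <- r$qc$n_spikes
    row$adapted_directions <- r$qc$adapted_directions
    row$max_frac_clipped <- max(r$qc$frac_clipped)
    row$undefined_pref <- paste(r$qc$undefined_pref, collapse = ";")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.bm_analysis <- function(x, ...) {
  cat(sprintf("<bm_analysis> %d cell(s) analyzed", length(x$cells)))
  if (length(x$qc$failed_cells))
    cat(sprintf(", %d failed", length(x$qc$failed_cells)))
  cat("\n")
  print(head(cell_results_table(x)[, c("cell_id", "dO_total", "dO_thalamic",
                                       "dO_cortical", "scale_contra",
                                       "scale_ipsi")]))
  invisible(x)
}

#' @export
summary.bm_analysis <- function(object, ...) {
  tab <- cell_results_table(object)
  metrics <- c("dO_total", "dO_thalamic", "dO_cortical",
               "scale_contra", "scale_ipsi",
               "ci_ratio_total", "ci_ratio_thalamic")
  out <- lapply(metrics, function(m) {
    x <- tab[[m]]
    if (all(is.na(x))) list(n = 0L, mean = NA_real_, sem = NA_real_)
    else mean_sem(x)
  })
  names(out) <- metrics
  structure(list(n_cells = nrow(tab), metrics = out),
            class = "summary.bm_analysis")
}

#' @export
print.summary.bm_analysis <- function(x, ...) {
  cat(sprintf("Analysis of %d cell(s); mean +/- SEM:\n", x$n_cells))
  for (m in names(x$metrics)) {
    s <- x$metrics[[m]]
    if (s$n == 0L) next
    cat(sprintf("  %-18s %7.3f +/- %-7.3f (n=%d)\n", m, s$mean,
                s$sem %||% NA, s$n))
  }
  invisible(x)
}

#' Simulate, analyze and compare young and adult cohorts
#'
#' End-to-end demonstration: generates voltage-clamp cohorts (young n = 26,
#' adult n = 15) and current-clamp cohorts (young n = 25, adult n = 14)
#' with the cohort presets, analyzes them, runs the cohort test battery on
#' the voltage-clamp results, compares the membrane-potential inter-ocular
#' differences across ages, and juxtaposes recovered metrics with generator
#' truth.
#'
#' @param seed master seed; every cohort derives its seed from it.
#' @param n_young_vc,n_adult_vc,n_young_cc,n_adult_cc cohort sizes.
#' @param noise_sd optional noise override passed to the generator.
#' @param config a \code{\link{bm_config}}.
#' @return object of class \code{bm_demo} with the analyses, truth tables,
#'   cohort comparison and the membrane-potential test battery.
#' @export
run_full_demo <- function(seed = 1L, n_young_vc = 26L, n_adult_vc = 15L,
                          n_young_cc = 25L, n_adult_cc = 14L,
                          noise_sd = NULL, config = bm_config()) {
  specs <- list(
    young_vc = list(cohort = "young", n = n_young_vc, mode = "voltage_clamp"),
    adult_vc = list(cohort = "adult", n = n_adult_vc, mode = "voltage_clamp"),
    young_cc = list(cohort = "young", n = n_young_cc, mode = "current_clamp"),
    adult_cc = list(cohort = "adult", n = n_adult_cc, mode = "current_clamp"))
  analyses <- list()
  truths <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$n == 0L) next
    gc_seed <- (as.integer(seed) + i * 7919L) %% .Machine$integer.max
    gcfg <- generator_config(sp$cohort, n_cells = sp$n, seed = gc_seed,
                             clamp_mode = sp$mode, noise_sd = noise_sd)
    sim <- generate_cohort(gcfg)
    analyses[[names(specs)[i]]] <- analyze_dataset(sim$dataset, config = config)
    truths[[names(specs)[i]]] <- sim$truth
  }
  comparison <- compare_cohorts(analyses$young_vc$cells,
                                analyses$adult_vc$cells)
  # membrane-potential (current clamp) inter-ocular difference battery
  vm_young <- metric_vector(analyses$young_cc$cells, "dO", "total")
  vm_adult <- metric_vector(analyses$adult_cc$cells, "dO", "total")
  vm_tests <- list(
    ks_young_vs_adult = ks_two_sample(vm_young[!is.na(vm_young)],
                                      vm_adult[!is.na(vm_adult)]),
    ks_young_vs_uniform = ks_vs_uniform(vm_young),
    ks_adult_vs_uniform = ks_vs_uniform(vm_adult),
    young = mean_sem(vm_young), adult = mean_sem(vm_adult))

  structure(list(seed = seed, analyses = analyses, truths = truths,
                 comparison = comparison, vm_tests = vm_tests),
            class = "bm_demo")
}

#' @export
print.bm_demo <- function(x, ...) {
  cat(sprintf("End-to-end demo (seed %d)\n", x$seed))
  cat("\n== Membrane potential (current clamp) ==\n")
  cat(sprintf("  dO young: %.1f +/- %.1f (n=%d); adult: %.1f +/- %.1f (n=%d)\n",
              x$vm_tests$young$mean, x$vm_tests$young$sem, x$vm_tests$young$n,
              x$vm_tests$adult$mean, x$vm_tests$adult$sem, x$vm_tests$adult$n))
  cat(sprintf("  K-S young vs adult: D=%.3f p=%.4g\n",
              x$vm_tests$ks_young_vs_adult$statistic,
              x$vm_tests$ks_young_vs_adult$p))
  cat(sprintf("  K-S young vs Uniform(0,90): D=%.3f p=%.4g\n",
              x$vm_tests$ks_young_vs_uniform$statistic,
              x$vm_tests$ks_young_vs_uniform$p))
  cat("\n== EPSC cohorts (voltage clamp) ==\n")
  print(x$comparison)
  cat("\n== Recovered vs generator truth (voltage clamp) ==\n")
  for (g in c("young_vc", "adult_vc")) {
    rec <- metric_vector(x$analyses[[g]]$cells, "dO", "thalamic")
    cat(sprintf("  %s: recovered mean dO_thalamic %.1f vs truth %.1f\n",
                g, mean(rec, na.rm = TRUE), mean(x$truths[[g]]$dO_thal)))
  }
  invisible(x)
}
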