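#' Run the full dilution-replicate analysis
#'
#' Convenience wrapper chaining the pipeline stages: (optional) imputation of
#' missing reference-gene Cq values, per-amplicon collinear standard-curve
#' fitting, outlier flagging, relative quantification, reference-gene
#' normalization, group-comparison statistics, and (optionally) export of all
#' tables and figures. Precalculated-expression datasets skip straight to
#' statistics.
#'
#' @param ds a `qpcr_dataset` (either mode).
#' @param impute impute missing reference-gene Cq values first (cq mode).
#' @param impute_k donor-pool size for imputation.
#' @param seed seed for the imputation donor draw.
#' @param outlier_threshold absolute studentized-residual cutoff for flagging.
#' @param scaling_group group scaled to unit geometric-mean expression;
#'   default first group in file order.
#' @param stats a [stats_config()], or `NULL` to skip testing.
#' @param outdir if non-`NULL`, write all outputs there via [export_all()].
#' @param dataset_name file-name prefix used when exporting.
#' @param plot a [plot_config()] used when exporting.
#' @return list with elements `dataset`, `fits` (cq mode), `imputation`
#'   report (when run), `expression`, `stats`, and `files` (when exported).
#' @export
#' @examples
#' sim <- simulate_dilrep(ground_truth(noise_sd = 0, seed = 7))
#' res <- run_analysis(sim$dataset, stats = stats_config())
#' res$expression
run_analysis <- function(ds, impute = FALSE, impute_k = 5, seed = 1L,
                         outlier_threshold = 3, scaling_group = NULL,
                         stats = stats_config(), outdir = NULL,
                         dataset_name = "qpcr", plot = plot_config()) {
  stopifnot(inherits(ds, "qpcr_dataset"))
  res <- list(dataset = ds)
  if (ds$mode == "cq") {
    if (impute) {
      imp <- impute_reference_cq(ds, k_donors = impute_k, seed = seed)
      res$dataset <- ds <- imp$dataset
      res$imputation <- imp$report
    }
    fits <- fit_all_amplicons(ds)
    fits <- lapply(fits, flag_outliers, threshold = outlier_threshold)
    res$fits <- fits
    res$expression <- normalize_expression(fits, ds, scaling_group = scaling_group)
  } else {
    res$expression <- passthrough_precalc(ds)
  }
  if (!is.null(stats)) {
    res$stats <- run_tests(res$expression, stats)
  }
  if (!is.null(outdir)) {
    res$files <- export_all(outdir, dataset_name, res$expression,
                            fits = res$fits, stats = res$stats,
                            ds = if (ds$mode == "cq") ds else NULL, cfg = plot)
  }
  res
}
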