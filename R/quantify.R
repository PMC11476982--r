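#' Relative template quantities from a fitted standard curve
#'
#' The collinear fit gives every replicate an intercept `a_r`, the Cq its
#' undiluted template would produce. Template quantity relative to a chosen
#' reference replicate follows from the intercept difference divided by the
#' shared slope: `log10(Q_r) = (a_ref - a_r) / slope`, so `Q_ref = 1` and a
#' replicate sitting one cycle later than the reference at efficiency 2 has
#' half its template.
#'
#' @param fit an `amplicon_fit`.
#' @param reference_replicate replicate (sample) name serving as the unit;
#'   default: the first fitted replicate.
#' @return tibble with columns `sample` and `rq` (linear-scale relative
#'   quantity).
#' @export
relative_quantities <- function(fit, reference_replicate = NULL) {
  stopifnot(inherits(fit, "amplicon_fit"))
  a <- fit$intercepts
  ref <- reference_replicate %||% names(a)[1]
  if (!ref %in% names(a)) {
    stop("reference replicate ", ref, " was not fitted for amplicon ",
         fit$amplicon, call. = FALSE)
  }
  tibble::tibble(
    sample = names(a),
    rq = 10^((a[[ref]] - unname(a)) / fit$slope_b)
  )
}

#' Reference-normalized expression from per-amplicon relative quantities
#'
#' Each replicate's normalization factor is the geometric mean of its
#' reference-gene quantities (arithmetic averaging of reference genes is a
#' known error source). Normalized expression `N = Q_goi / geomean(Q_rg)` is
#' then rescaled so that the geometric mean of N over the scaling-reference
#' group equals 1 (its mean log2 expression is 0); the choice of scaling
#' group moves all values by a common factor and leaves every group contrast
#' untouched.
#'
#' @param fits named list of `amplicon_fit` objects covering all amplicons.
#' @param ds the `qpcr_dataset` the fits came from.
#' @param scaling_group group whose geometric mean becomes 1; default: first
#'   group in file order.
#' @return an `expression_table`: tibble with columns `sample`, `group`,
#'   `replicate_id`, `pair_id`, `gene`, `norm_expr`, `log2_norm_expr`, with
#'   attributes `scaling_reference` (group name) and `rq` (wide tibble of raw
#'   relative quantities per amplicon).
#' @export
normalize_expression <- function(fits, ds, scaling_group = NULL) {
  stopifnot(inherits(ds, "qpcr_dataset"), ds$mode == "cq")
  missing_amp <- setdiff(ds$amplicons, names(fits))
  if (length(missing_amp) > 0L) {
    stop("no fit supplied for amplicon(s): ", paste(missing_amp, collapse = ", "),
         call. = FALSE)
  }
  meta <- dplyr::distinct(ds$wells[c("sample", "group", "replicate_id", "pair_id")])
  scaling_group <- scaling_group %||% meta$group[1]
  if (!scaling_group %in% meta$group) {
    stop("scaling group ", scaling_group, " not present in the data", call. = FALSE)
  }

  rq_long <- dplyr::bind_rows(lapply(ds$amplicons, function(a) {
    q <- relative_quantities(fits[[a]])
    q$amplicon <- a
    q
  }))
  rq_wide <- tidyr::pivot_wider(rq_long, names_from = "amplicon", values_from = "rq")

  nf <- rq_long[rq_long$amplicon %in% ds$reference_genes, ]
  no_rg <- setdiff(unique(rq_long$sample), unique(nf$sample))
  if (length(no_rg) > 0L) {
    stop("replicate(s) without any fitted reference gene cannot be normalized: ",
         paste(no_rg, collapse = ", "), call. = FALSE)
  }
  n_rg_per <- tapply(nf$amplicon, nf$sample, length)
  if (any(n_rg_per < length(ds$reference_genes))) {
    warning("some replicates are missing part of the reference-gene panel; ",
            "their normalization factor uses the available reference genes only",
            call. = FALSE)
  }
  nf <- tapply(nf$rq, nf$sample, geometric_mean)

  goi <- genes_of_interest(ds)
  expr <- dplyr::bind_rows(lapply(goi, function(g) {
    q <- rq_long[rq_long$amplicon == g, ]
    all_samples <- meta$sample
    lost <- setdiff(all_samples, q$sample)
    if (length(lost) > 0L) {
      warning("gene ", g, ": replicate(s) without a usable dilution series ",
              "dropped for this gene: ", paste(lost, collapse = ", "),
              call. = FALSE)
    }
    n <- q$rq / as.numeric(nf[q$sample])
    out <- tibble::tibble(sample = q$sample, gene = g, norm_expr = n)
    out <- dplyr::left_join(out, meta, by = "sample")
    scale_ref <- out$norm_expr[out$group == scaling_group]
    if (length(scale_ref) == 0L) {
      stop("gene ", g, ": no replicate of scaling group ", scaling_group,
           " available", call. = FALSE)
    }
    out$norm_expr <- out$norm_expr / geometric_mean(scale_ref)
    out
  }))
  expr$log2_norm_expr <- log2(expr$norm_expr)
  expr <- expr[c("sample", "group", "replicate_id", "pair_id", "gene",
                 "norm_expr", "log2_norm_expr")]
  structure(expr, class = c("expression_table", class(expr)),
            scaling_reference = scaling_group, rq = rq_wide)
}

#' Carry precalculated relative expression into the pipeline representation
#'
#' Precalculated linear-scale expression values skip curve fitting and
#' normalization; they are taken as given, the log2 column is added, and the
#' same statistics and plotting stages apply.
#'
#' @param ds a precalc-mode `qpcr_dataset`.
#' @return an `expression_table` (no rescaling is applied; the
#'   `scaling_reference` attribute is `NA`).
#' @export
passthrough_precalc <- function(ds) {
  stopifnot(inherits(ds, "qpcr_dataset"))
  if (ds$mode != "precalc") {
    stop("passthrough_precalc() expects a precalculated-expression dataset",
         call. = FALSE)
  }
  expr <- tibble::tibble(
    sample = ds$wells$sample, group = ds$wells$group,
    replicate_id = ds$wells$replicate_id, pair_id = ds$wells$pair_id,
    gene = ds$wells$amplicon,
    norm_expr = ds$wells$value,
    log2_norm_expr = log2(ds$wells$value)
  )
  structure(expr, class = c("expression_table", class(expr)),
            scaling_reference = NA_character_, rq = NULL)
}
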