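#' Fit the collinear dilution-replicate standard curve of one amplicon
#'
#' Every biological replicate contributes its own short dilution series, and
#' all series are fit jointly by ordinary least squares with a single shared
#' slope (cycles per log10 dilution factor) and one intercept per replicate
#' (the replicate's Cq at dilution 1). The shared slope carries the
#' amplification efficiency, `E = 10^(1/slope)`; the intercept differences
#' carry the relative template quantities (see [relative_quantities()]).
#'
#' Replicates with fewer than two distinct observed dilutions cannot
#' constrain the slope and are excluded from the fit with a warning.
#'
#' @param ds a cq-mode `qpcr_dataset`.
#' @param amplicon amplicon name to fit.
#' @param exclude_wells optional logical vector (or tibble of wells with an
#'   `outlier` column) marking wells to drop before fitting; used by
#'   [refit_without_outliers()].
#' @return object of class `amplicon_fit` with elements `slope_b`, `slope_se`,
#'   `efficiency`, `r_squared`, `intercepts` (named by replicate), `wells`
#'   (per-well fitted values, residuals, externally studentized residuals and
#'   outlier flags), `df_residual`, `n_wells_used`.
#' @export
fit_collinear <- function(ds, amplicon, exclude_wells = NULL) {
  stopifnot(inherits(ds, "qpcr_dataset"))
  if (ds$mode != "cq") stop("standard curves require a cq-mode dataset", call. = FALSE)
  if (!amplicon %in% ds$amplicons) {
    stop("unknown amplicon: ", amplicon, call. = FALSE)
  }
  w <- ds$wells[ds$wells$amplicon == amplicon & !is.na(ds$wells$cq), ]
  if (!is.null(exclude_wells)) {
    keep <- !(paste(w$sample, w$dilution) %in% exclude_wells)
    w <- w[keep, ]
  }
  n_dil <- tapply(w$dilution, w$sample, function(d) length(unique(d)))
  ok <- names(n_dil)[n_dil >= 2L]
  dropped <- setdiff(unique(w$sample), ok)
  if (length(dropped) > 0L) {
    warning("amplicon ", amplicon, ": replicate(s) with < 2 observed dilutions ",
            "excluded from the standard curve: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  w <- w[w$sample %in% ok, ]
  if (nrow(w) == 0L || length(ok) == 0L) {
    stop("amplicon ", amplicon, ": no fit-eligible replicate", call. = FALSE)
  }
  if (length(unique(w$dilution)) < 2L) {
    stop("amplicon ", amplicon, ": a single dilution level overall leaves the ",
         "slope unidentifiable (rank-deficient design)", call. = FALSE)
  }

  w$log10d <- log10(w$dilution)
  # keep replicate order as it appears in the data (= input file order)
  w$rep_f <- factor(w$sample, levels = unique(w$sample))
  fit <- if (nlevels(w$rep_f) > 1L) {
    stats::lm(cq ~ 0 + rep_f + log10d, data = w)
  } else {
    stats::lm(cq ~ log10d, data = w)  # a lone series reduces to simple regression
  }
  coefs <- stats::coef(fit)
  slope <- unname(coefs[["log10d"]])
  intercepts <- coefs[names(coefs) != "log10d"]
  names(intercepts) <- sub("^rep_f", "", names(intercepts))
  if (identical(names(intercepts), "(Intercept)")) names(intercepts) <- levels(w$rep_f)
  if (!is.finite(slope) || slope <= 0) {
    warning("amplicon ", amplicon, ": fitted slope is not positive (",
            format(slope, digits = 4), "); Cq should rise with dilution",
            call. = FALSE)
  }
  efficiency <- 10^(1 / slope)
  if (is.finite(efficiency) && (efficiency > 2.1 || efficiency < 1.6)) {
    warning("amplicon ", amplicon, ": estimated efficiency ",
            format(efficiency, digits = 4),
            " outside the usual range [1.6, 2.1]; check the dilution series",
            call. = FALSE)
  }
  res <- stats::residuals(fit)
  sst <- sum((w$cq - mean(w$cq))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  df_res <- stats::df.residual(fit)
  rstud <- if (df_res >= 2L) suppressWarnings(stats::rstudent(fit)) else rep(NA_real_, nrow(w))
  # deleting a well can leave a perfect fit; the 0/0 case means the well is
  # either perfectly consistent (residual ~ 0) or infinitely discrepant
  nan_rs <- is.nan(rstud)
  if (any(nan_rs)) {
    scale_tol <- 1e-8 * max(1, stats::sd(w$cq))
    rstud[nan_rs] <- ifelse(abs(res[nan_rs]) > scale_tol,
                            sign(res[nan_rs]) * Inf, 0)
  }

  wells <- tibble::tibble(
    sample = w$sample, group = w$group, replicate_id = w$replicate_id,
    dilution = w$dilution, log10d = w$log10d, cq = w$cq,
    fitted = unname(stats::fitted(fit)), residual = unname(res),
    rstudent = unname(rstud), outlier = FALSE
  )

  structure(list(
    amplicon = amplicon,
    slope_b = slope,
    slope_se = sqrt(diag(suppressWarnings(stats::vcov(fit))))[["log10d"]],
    efficiency = efficiency,
    r_squared = r2,
    intercepts = intercepts,
    wells = wells,
    df_residual = df_res,
    n_wells_used = nrow(w),
    refitted = FALSE
  ), class = "amplicon_fit")
}

#' Fit standard curves for every amplicon of a dataset
#'
#' @param ds a cq-mode `qpcr_dataset`.
#' @return named list of [fit_collinear()] results, in amplicon order.
#' @export
fit_all_amplicons <- function(ds) {
  stats::setNames(lapply(ds$amplicons, function(a) fit_collinear(ds, a)),
                  ds$amplicons)
}

#' Flag possible outlier wells of a fitted standard curve
#'
#' Wells whose externally studentized residual exceeds `threshold` in absolute
#' value are flagged. Flags are advisory: nothing is removed. Refitting
#' without flagged wells happens only on explicit request through
#' [refit_without_outliers()], and at most once.
#'
#' @param fit an `amplicon_fit`.
#' @param threshold absolute studentized-residual cutoff, default 3.
#' @return the fit with its `wells$outlier` column updated.
#' @export
flag_outliers <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "amplicon_fit"))
  if (fit$df_residual < 3L) {
    warning("amplicon ", fit$amplicon, ": fewer than 3 residual degrees of ",
            "freedom; outlier flagging skipped", call. = FALSE)
    fit$wells$outlier <- FALSE
    return(fit)
  }
  # studentizing numerically-zero residuals can produce large t values on
  # noiseless data; require the raw residual to be non-negligible too
  scale_tol <- 1e-8 * max(1, stats::sd(fit$wells$cq))
  fit$wells$outlier <- !is.na(fit$wells$rstudent) &
    abs(fit$wells$rstudent) > threshold &
    abs(fit$wells$residual) > scale_tol
  fit
}

#' Refit a standard curve without its flagged outlier wells
#'
#' @param fit an `amplicon_fit` with outlier flags (see [flag_outliers()]).
#' @param ds the dataset the fit came from.
#' @return a fresh `amplicon_fit` with the flagged wells excluded.
#' @export
refit_without_outliers <- function(fit, ds) {
  stopifnot(inherits(fit, "amplicon_fit"))
  if (isTRUE(fit$refitted)) {
    stop("this fit is already the result of outlier removal; wells are ",
         "removed at most once", call. = FALSE)
  }
  flagged <- fit$wells[fit$wells$outlier, ]
  if (nrow(flagged) == 0L) return(fit)
  out <- fit_collinear(ds, fit$amplicon,
                       exclude_wells = paste(flagged$sample, flagged$dilution))
  out$refitted <- TRUE
  out
}

#' @export
print.amplicon_fit <- function(x, ...) {
  cat("<amplicon_fit: ", x$amplicon, ">\n", sep = "")
  cat(sprintf("  slope %.4f cycles/log10(D) (SE %.4f), E = %.4f, R^2 = %.5f\n",
              x$slope_b, x$slope_se, x$efficiency, x$r_squared))
  cat("  ", length(x$intercepts), " replicates, ", x$n_wells_used, " wells, ",
      sum(x$wells$outlier), " flagged outlier(s)\n", sep = "")
  invisible(x)
}

#' Summarize a list of amplicon fits as a table
#'
#' @param fits named list of `amplicon_fit` objects.
#' @return tibble with one row per amplicon (slope, SE, efficiency, R^2,
#'   replicate and well counts, outlier count).
#' @export
fits_summary <- function(fits) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      amplicon = f$amplicon, slope = f$slope_b, slope_se = f$slope_se,
      efficiency = f$efficiency, r_squared = f$r_squared,
      n_replicates = length(f$intercepts), n_wells = f$n_wells_used,
      n_outliers_flagged = sum(f$wells$outlier)
    )
  }))
}

#' Derive the Cq-Cq line of a gene of interest against a reference gene
#'
#' In the dilution-replicate design the diagnostic Cq-Cq plot shows, for each
#' replicate, the gene-of-interest Cq against the reference-gene Cq across the
#' dilution series. Because both amplicons share the same dilution grid, the
#' line's slope is the ratio of the two standard-curve slopes and its
#' per-replicate vertical offset is `a_goi - slope_ratio * a_rg`.
#'
#' @param fit_goi,fit_rg `amplicon_fit` objects for the gene of interest and
#'   the reference gene.
#' @return object of class `cqcq_fit`: `goi`, `rg`, `slope_ratio`, `offsets`
#'   (named by replicate, cycles).
#' @export
cqcq_fit <- function(fit_goi, fit_rg) {
  stopifnot(inherits(fit_goi, "amplicon_fit"), inherits(fit_rg, "amplicon_fit"))
  common <- intersect(names(fit_goi$intercepts), names(fit_rg$intercepts))
  if (length(common) == 0L) {
    stop("no replicate was fit for both ", fit_goi$amplicon, " and ",
         fit_rg$amplicon, call. = FALSE)
  }
  ratio <- fit_goi$slope_b / fit_rg$slope_b
  offsets <- fit_goi$intercepts[common] - ratio * fit_rg$intercepts[common]
  structure(list(goi = fit_goi$amplicon, rg = fit_rg$amplicon,
                 slope_ratio = ratio, offsets = offsets),
            class = "cqcq_fit")
}

#' Classical single-standard-curve efficiency
#'
#' The textbook standard-curve method regresses Cq on log10(concentration) of
#' a dilution series and reports `E = 10^(-1/slope)`. Provided as a
#' comparison utility; the main pipeline estimates efficiency from the
#' collinear fit instead. The two conventions agree: with concentration taken
#' as the reciprocal of the dilution factor, the classical slope is the
#' negative of the collinear slope and both formulas give the same E.
#'
#' @param concentration relative template concentrations (> 0).
#' @param cq quantification cycles at those concentrations.
#' @return estimated efficiency (per-cycle amplification factor).
#' @export
#' @examples
#' conc <- c(1, 0.2, 0.04)
#' classical_efficiency(conc, 20 - 3.321928 * log10(conc)) # 2
classical_efficiency <- function(concentration, cq) {
  if (length(concentration) != length(cq)) {
    stop("concentration and cq must have the same length", call. = FALSE)
  }
  if (length(concentration) < 3L) {
    stop("the classical standard curve needs at least 3 points", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("concentrations must not all be identical", call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(cq ~ log10(concentration)))[2])
  10^(-1 / slope)
}
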