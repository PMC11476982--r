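#' Impute missing reference-gene Cq values by weighted predictive mean matching
#'
#' Missing wells occur in practice (pipetting failures, off-scale reactions).
#' Only reference-gene wells are imputed — a gene of interest with missing
#' wells simply loses that replicate downstream. For each missing
#' reference-gene Cq the procedure:
#'
#' 1. regresses the observed Cq values of that amplicon on the predictors
#'    available in the incomplete well's row (log10 dilution factor plus the
#'    Cq values of all other amplicons measured in the same reaction row);
#' 2. predicts the missing cell and all observed cells from that model;
#' 3. forms a donor pool of the `k_donors` observed wells whose predictions
#'    are closest to the missing cell's prediction;
#' 4. draws one donor with probability proportional to the inverse of its
#'    prediction distance and imputes the donor's *observed* Cq.
#'
#' Because imputed values are always observed values, imputation never
#' extrapolates beyond the observed Cq range of the amplicon. The procedure
#' is deterministic for a fixed `seed`. Imputing many missing values degrades
#' the analysis, so imputation refuses to run when more than half of a
#' reference gene's wells are missing and warns above 30 %.
#'
#' @param ds a cq-mode `qpcr_dataset`.
#' @param k_donors size of the donor pool, default 5.
#' @param seed integer seed for the weighted donor draw.
#' @return list with elements `dataset` (completed) and `report` (tibble of
#'   imputed cells: sample, dilution, amplicon, imputed Cq, donor count, plus
#'   the pre-imputation missing fraction per column as attribute
#'   `fraction_missing`).
#' @export
impute_reference_cq <- function(ds, k_donors = 5, seed = 1L) {
  stopifnot(inherits(ds, "qpcr_dataset"))
  if (ds$mode != "cq") stop("imputation applies to cq-mode datasets", call. = FALSE)
  w <- ds$wells
  goi <- genes_of_interest(ds)
  miss_goi <- is.na(w$cq) & w$amplicon %in% goi
  if (any(miss_goi)) {
    warning(sum(miss_goi), " missing gene-of-interest Cq value(s) are left as ",
            "is; only reference genes are imputed", call. = FALSE)
  }

  # reaction-row layout: one row per (sample, dilution), one column per amplicon
  wide <- tidyr::pivot_wider(w[c("sample", "dilution", "amplicon", "cq")],
                             names_from = "amplicon", values_from = "cq")
  wide$log10d <- log10(wide$dilution)

  frac_missing <- vapply(ds$reference_genes,
                         function(a) mean(is.na(wide[[a]])), numeric(1))
  for (a in ds$reference_genes) {
    if (frac_missing[[a]] > 0.5) {
      stop("reference gene ", a, ": ", round(100 * frac_missing[[a]]),
           "% of Cq values are missing; imputation refused (more than 50% ",
           "missing cannot be imputed reliably)", call. = FALSE)
    }
    if (frac_missing[[a]] > 0.3) {
      warning("reference gene ", a, ": ", round(100 * frac_missing[[a]]),
              "% of Cq values are missing; imputation results may be unreliable",
              call. = FALSE)
    }
  }

  report <- tibble::tibble(sample = character(), dilution = numeric(),
                           amplicon = character(), imputed_cq = numeric(),
                           donor_count = integer())
  if (!anyNA(wide[ds$reference_genes])) {
    attr(report, "fraction_missing") <- frac_missing
    return(list(dataset = ds, report = report))
  }

  withr::with_seed(seed, {
    for (a in ds$reference_genes) {
      miss_idx <- which(is.na(wide[[a]]))
      if (length(miss_idx) == 0L) next
      obs_idx <- which(!is.na(wide[[a]]))
      if (length(obs_idx) < max(k_donors + 1, 5)) {
        stop("reference gene ", a, ": only ", length(obs_idx), " observed ",
             "wells; at least ", max(k_donors + 1, 5),
             " are needed to form a donor pool", call. = FALSE)
      }
      predictors <- c("log10d", setdiff(ds$amplicons, a))
      for (m in miss_idx) {
        avail <- predictors[!is.na(wide[m, predictors])]
        if (length(avail) == 0L) avail <- "log10d"
        train <- obs_idx[stats::complete.cases(wide[obs_idx, avail])]
        if (length(train) < length(avail) + 2L) {
          # fall back to the dilution trend alone if covariates knock out
          # too many training rows
          avail <- "log10d"
          train <- obs_idx
        }
        form <- stats::reformulate(avail, response = a)
        mod <- stats::lm(form, data = wide[train, c(a, avail)])
        yhat_obs <- stats::predict(mod, newdata = wide[train, avail])
        yhat_mis <- stats::predict(mod, newdata = wide[m, avail])
        d <- abs(yhat_obs - yhat_mis)
        pool_n <- min(k_donors, length(train))
        pool <- train[order(d, seq_along(d))][seq_len(pool_n)]
        pool_d <- sort(d, method = "radix")[seq_len(pool_n)]
        wts <- 1 / (pool_d + 1e-8)
        donor <- pool[sample.int(pool_n, 1L, prob = wts / sum(wts))]
        wide[m, a] <- wide[donor, a]
        report <- dplyr::bind_rows(report, tibble::tibble(
          sample = wide$sample[m], dilution = wide$dilution[m], amplicon = a,
          imputed_cq = wide[[a]][m], donor_count = pool_n
        ))
      }
    }
  })

  long <- tidyr::pivot_longer(wide[c("sample", "dilution", ds$amplicons)],
                              dplyr::all_of(ds$amplicons),
                              names_to = "amplicon", values_to = "cq")
  out <- ds
  key_w <- paste(out$wells$sample, out$wells$dilution, out$wells$amplicon)
  key_l <- paste(long$sample, long$dilution, long$amplicon)
  out$wells$cq <- long$cq[match(key_w, key_l)]
  attr(report, "fraction_missing") <- frac_missing
  list(dataset = validate_qpcr_dataset(out), report = report)
}
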