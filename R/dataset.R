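#' qPCR dataset container
#'
#' A `qpcr_dataset` holds either raw quantification-cycle (Cq) values from a
#' dilution-replicate experiment (`mode = "cq"`) or precalculated linear-scale
#' relative expression values (`mode = "precalc"`), together with the amplicon
#' order of the input file and the set of designated reference genes.
#'
#' In `cq` mode the well table has one row per well:
#' `sample` (the original replicate name), `group`, `replicate_id`, `pair_id`,
#' `dilution` (dilution factor, 1 = undiluted), `amplicon` and `cq` (possibly
#' `NA` for missing wells). In `precalc` mode the table has one row per
#' (replicate, gene) with a strictly positive `value` column.
#'
#' @param wells tibble of wells (cq mode) or expression values (precalc mode).
#' @param amplicons character, amplicon names in input-file column order.
#' @param reference_genes character, subset of `amplicons` (cq mode).
#' @param mode `"cq"` or `"precalc"`.
#' @param pairs_present logical, whether the Pairs column carried information.
#' @return object of class `qpcr_dataset`.
#' @export
new_qpcr_dataset <- function(wells, amplicons, reference_genes = character(),
                             mode = c("cq", "precalc"), pairs_present = FALSE) {
  mode <- match.arg(mode)
  ds <- structure(
    list(
      wells = wells,
      amplicons = amplicons,
      reference_genes = reference_genes,
      mode = mode,
      pairs_present = pairs_present
    ),
    class = "qpcr_dataset"
  )
  validate_qpcr_dataset(ds)
}

validate_qpcr_dataset <- function(ds) {
  w <- ds$wells
  if (ds$mode == "cq") {
    if (length(ds$reference_genes) == 0L) {
      stop("cq-mode datasets need at least one designated reference gene", call. = FALSE)
    }
    if (!all(ds$reference_genes %in% ds$amplicons)) {
      stop("reference genes not found among amplicon columns: ",
           paste(setdiff(ds$reference_genes, ds$amplicons), collapse = ", "),
           call. = FALSE)
    }
    # input convention: reference genes come first, genes of interest after
    n_rg <- length(ds$reference_genes)
    if (!setequal(ds$amplicons[seq_len(n_rg)], ds$reference_genes)) {
      stop("reference-gene columns must precede gene-of-interest columns; ",
           "found reference genes at non-leading positions", call. = FALSE)
    }
    if (any(!is.finite(w$dilution) | w$dilution <= 0)) {
      stop("all dilution factors must be positive numbers", call. = FALSE)
    }
    dup <- duplicated(w[c("sample", "dilution", "amplicon")])
    if (any(dup)) {
      stop("duplicate wells for (replicate, dilution, amplicon): ",
           paste(utils::head(unique(paste(w$sample[dup], w$dilution[dup],
                                          w$amplicon[dup], sep = "/")), 3L),
                 collapse = ", "),
           call. = FALSE)
    }
    eligible <- fit_eligible_replicates(ds)
    n_eligible <- vapply(ds$amplicons, function(a) length(eligible[[a]]), integer(1))
    if (any(n_eligible == 0L)) {
      stop("no fit-eligible replicate (>= 2 distinct dilutions with observed Cq) for amplicon(s): ",
           paste(ds$amplicons[n_eligible == 0L], collapse = ", "), call. = FALSE)
    }
  } else {
    if (any(!is.finite(w$value) | w$value <= 0)) {
      stop("precalculated relative expression values must be positive ",
           "(log transformation is applied downstream)", call. = FALSE)
    }
  }
  ds
}

# per-amplicon character vector of samples with >= 2 distinct observed dilutions
fit_eligible_replicates <- function(ds) {
  stopifnot(ds$mode == "cq")
  w <- ds$wells[!is.na(ds$wells$cq), ]
  lapply(stats::setNames(ds$amplicons, ds$amplicons), function(a) {
    wa <- w[w$amplicon == a, ]
    tab <- tapply(wa$dilution, wa$sample, function(d) length(unique(d)))
    names(tab)[tab >= 2L]
  })
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  if (x$mode == "cq") {
    n_samp <- length(unique(x$wells$sample))
    cat("<qpcr_dataset: Cq mode>\n")
    cat("  ", n_samp, " replicates in ", length(unique(x$wells$group)), " groups; ",
        length(unique(x$wells$dilution)), " dilution levels\n", sep = "")
    cat("  amplicons: ", paste(x$amplicons, collapse = ", "),
        " (reference: ", paste(x$reference_genes, collapse = ", "), ")\n", sep = "")
    cat("  missing Cq wells: ", sum(is.na(x$wells$cq)), "\n", sep = "")
  } else {
    cat("<qpcr_dataset: precalculated relative expression>\n")
    cat("  ", length(unique(x$wells$sample)), " replicates; genes: ",
        paste(x$amplicons, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' List genes of interest of a dataset
#'
#' In `cq` mode these are the amplicons not designated as reference genes; in
#' `precalc` mode every column is a gene of interest.
#'
#' @param ds a `qpcr_dataset`.
#' @return character vector.
#' @export
genes_of_interest <- function(ds) {
  setdiff(ds$amplicons, ds$reference_genes)
}
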