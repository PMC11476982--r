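#' Geometric mean
#'
#' Computed as the exponential of the mean of logs, so it is only defined for
#' strictly positive input. Used to combine relative quantities of multiple
#' reference genes into one normalization factor per replicate.
#'
#' @param x numeric vector, all values > 0.
#' @param na.rm drop missing values before averaging.
#' @return length-one numeric.
#' @export
#' @examples
#' geometric_mean(c(2, 8)) # 4
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometric_mean() requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

# significance label from an adjusted p-value (conventional asterisk scheme)
p_to_asterisks <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "p<0.001", sprintf("p=%.3f", p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
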