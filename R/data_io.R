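#' Detect the CSV dialect of an input file
#'
#' Two dialects are supported: point decimal separator with comma field
#' separator, and comma decimal separator with semicolon field separator (the
#' common European regional convention). The decision is made from the header
#' line alone: a semicolon implies the European dialect, otherwise a comma
#' implies the point-decimal dialect.
#'
#' @param raw_text character scalar or vector of file lines; only the first
#'   non-empty line (the header) is inspected.
#' @return list with elements `field_sep` (`","` or `";"`) and `decimal_sep`
#'   (`"."` or `","`).
#' @export
#' @examples
#' detect_dialect("Replicates,Pairs,Dilution,GAPDH")
#' detect_dialect("Replicates;Pairs;Dilution;GAPDH")
detect_dialect <- function(raw_text) {
  if (length(raw_text) == 0L || !nzchar(raw_text[1])) {
    stop("empty input: no header line to inspect", call. = FALSE)
  }
  lines <- unlist(strsplit(raw_text, "\r?\n"))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty input: no header line to inspect", call. = FALSE)
  header <- lines[1]
  has_semi <- grepl(";", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_semi && !has_comma) {
    list(field_sep = ";", decimal_sep = ",")
  } else if (has_comma && !has_semi) {
    list(field_sep = ",", decimal_sep = ".")
  } else {
    stop("cannot determine CSV dialect from header line (need exactly one of ",
         "',' or ';' as field separator): ", dQuote(header), call. = FALSE)
  }
}

#' Split replicate names into group and replicate identifier
#'
#' Sample names carry the biological-replicate identifier as a suffix after
#' the last underscore: `"HG-3 WT_1"` is replicate `"1"` of group
#' `"HG-3 WT"`. Splitting at the *last* underscore lets group names themselves
#' contain underscores.
#'
#' @param name character vector of replicate names.
#' @return tibble with columns `group` and `replicate_id`.
#' @export
#' @examples
#' split_replicate_name(c("HG-3 WT_1", "ctrl_a_2"))
split_replicate_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([A-Za-z0-9]+)$", name))
  bad <- vapply(m, length, integer(1)) != 3L
  bad <- bad | vapply(m, function(x) length(x) == 3L && !nzchar(x[2]), logical(1))
  if (any(bad)) {
    stop("malformed replicate name(s) (need '<group>_<alphanumeric suffix>'): ",
         paste(unique(name[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    group = vapply(m, `[`, character(1), 2L),
    replicate_id = vapply(m, `[`, character(1), 3L)
  )
}

read_delim_dialect <- function(path) {
  raw <- readLines(path, warn = FALSE)
  dialect <- detect_dialect(raw)
  df <- utils::read.csv(text = raw, sep = dialect$field_sep,
                        dec = dialect$decimal_sep, check.names = FALSE,
                        colClasses = "character", na.strings = c("", "NA"),
                        strip.white = TRUE)
  list(df = df, dialect = dialect)
}

parse_numeric <- function(x, decimal_sep, what) {
  if (decimal_sep == ",") x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric ", what, " value(s): ",
         paste(utils::head(unique(x[bad]), 3L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a raw Cq table in the dilution-replicate layout
#'
#' The file must have columns `Replicates`, `Pairs`, `Dilution`, then one
#' column of Cq values per amplicon, reference genes first. Both CSV dialects
#' are auto-detected. Empty cells and the literal `NA` are read as missing Cq.
#'
#' @param path path to the CSV file.
#' @param reference_genes character, names of the reference-gene columns.
#'   Must be named explicitly; they are never guessed.
#' @return a [new_qpcr_dataset()] in `cq` mode.
#' @export
read_cq_table <- function(path, reference_genes) {
  if (missing(reference_genes) || length(reference_genes) == 0L) {
    stop("reference genes must be named explicitly (reference_genes =)", call. = FALSE)
  }
  parsed <- read_delim_dialect(path)
  df <- parsed$df
  mandatory <- c("Replicates", "Pairs", "Dilution")
  if (ncol(df) < 4L || !identical(names(df)[1:3], mandatory)) {
    stop("the first three columns must be named exactly ",
         paste(mandatory, collapse = ", "), "; found: ",
         paste(utils::head(names(df), 3L), collapse = ", "), call. = FALSE)
  }
  amplicons <- names(df)[-(1:3)]
  split <- split_replicate_name(df$Replicates)
  dilution <- parse_numeric(df$Dilution, parsed$dialect$decimal_sep, "Dilution")
  if (anyNA(dilution)) stop("missing dilution factor(s) in the Dilution column", call. = FALSE)
  pair_id <- as.character(df$Pairs)
  wells <- tibble::tibble(
    sample = rep(df$Replicates, times = length(amplicons)),
    group = rep(split$group, times = length(amplicons)),
    replicate_id = rep(split$replicate_id, times = length(amplicons)),
    pair_id = rep(pair_id, times = length(amplicons)),
    dilution = rep(dilution, times = length(amplicons)),
    amplicon = rep(amplicons, each = nrow(df)),
    cq = unlist(lapply(amplicons, function(a) {
      parse_numeric(df[[a]], parsed$dialect$decimal_sep, paste0("Cq (", a, ")"))
    }), use.names = FALSE)
  )
  new_qpcr_dataset(wells, amplicons, reference_genes, mode = "cq",
                   pairs_present = any(!is.na(pair_id)))
}

#' Read a table of precalculated relative expression values
#'
#' The simpler input layout: columns `Replicates` and `Pairs`, then one column
#' of linear-scale relative expression per gene of interest. Values must be
#' strictly positive because all statistics run on log-transformed data.
#'
#' @param path path to the CSV file.
#' @return a [new_qpcr_dataset()] in `precalc` mode.
#' @export
read_precalc_table <- function(path) {
  parsed <- read_delim_dialect(path)
  df <- parsed$df
  mandatory <- c("Replicates", "Pairs")
  if (ncol(df) < 3L || !identical(names(df)[1:2], mandatory)) {
    stop("the first two columns must be named exactly ",
         paste(mandatory, collapse = ", "), "; found: ",
         paste(utils::head(names(df), 2L), collapse = ", "), call. = FALSE)
  }
  genes <- names(df)[-(1:2)]
  split <- split_replicate_name(df$Replicates)
  pair_id <- as.character(df$Pairs)
  vals <- tibble::tibble(
    sample = rep(df$Replicates, times = length(genes)),
    group = rep(split$group, times = length(genes)),
    replicate_id = rep(split$replicate_id, times = length(genes)),
    pair_id = rep(pair_id, times = length(genes)),
    amplicon = rep(genes, each = nrow(df)),
    value = unlist(lapply(genes, function(g) {
      parse_numeric(df[[g]], parsed$dialect$decimal_sep, paste0("expression (", g, ")"))
    }), use.names = FALSE)
  )
  if (anyNA(vals$value)) {
    stop("missing relative expression values are not supported in precalculated input",
         call. = FALSE)
  }
  new_qpcr_dataset(vals, genes, character(), mode = "precalc",
                   pairs_present = any(!is.na(pair_id)))
}

#' Serialize a Cq-mode dataset back to the input CSV layout
#'
#' Used by the synthetic-data generator and by round-trip tests. Either
#' dialect can be requested; parsing the result reproduces the dataset.
#'
#' @param ds a `qpcr_dataset` in cq mode.
#' @param path output path.
#' @param dialect `"point"` (comma fields, point decimals) or `"comma"`
#'   (semicolon fields, comma decimals).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(ds, path, dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "qpcr_dataset"), ds$mode == "cq")
  w <- ds$wells
  keys <- unique(w[c("sample", "pair_id", "dilution")])
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    if (dialect == "comma") out <- gsub(".", ",", out, fixed = TRUE)
    out
  }
  cols <- c(list(Replicates = keys$sample,
                 Pairs = ifelse(is.na(keys$pair_id), "", keys$pair_id),
                 Dilution = fmt(keys$dilution)),
            stats::setNames(lapply(ds$amplicons, function(a) {
              wa <- w[w$amplicon == a, ]
              idx <- match(paste(keys$sample, keys$dilution),
                           paste(wa$sample, wa$dilution))
              fmt(wa$cq[idx])
            }), ds$amplicons))
  sep <- if (dialect == "point") "," else ";"
  lines <- c(paste(names(cols), collapse = sep),
             do.call(paste, c(unname(cols), list(sep = sep))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as CSV
#'
#' All output tables use the point-decimal, comma-field dialect regardless of
#' the input dialect, so downstream parsing is deterministic. Numeric columns
#' are written at full precision (write-then-read round-trips to at least 12
#' significant digits).
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, na = "")
  invisible(path)
}
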