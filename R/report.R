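#' Plot appearance configuration
#'
#' @param plot_type `"dots_all"` (every replicate), `"dots_mean_sd"`,
#'   `"bars_mean_sd"`, or `"box"`.
#' @param scale `"log2"` or `"linear"` display scale. Statistics are always
#'   computed from log2 values regardless of the displayed scale.
#' @param font_size base font size in points.
#' @param palette RColorBrewer palette name for group colours.
#' @param significance_style `"asterisks"` or `"p_values"`; with asterisks,
#'   bars are drawn for significant comparisons only, with p-values every
#'   tested comparison is labelled.
#' @param sig_bar_spacing vertical spacing of stacked significance bars as a
#'   fraction of the data range.
#' @param width,height image size in inches.
#' @param dpi raster resolution for PNG export.
#' @return object of class `plot_config`.
#' @export
plot_config <- function(plot_type = c("dots_all", "dots_mean_sd", "bars_mean_sd", "box"),
                        scale = c("log2", "linear"),
                        font_size = 12, palette = "Set2",
                        significance_style = c("asterisks", "p_values"),
                        sig_bar_spacing = 0.1,
                        width = 6, height = 4.5, dpi = 300) {
  plot_type <- match.arg(plot_type)
  scale <- match.arg(scale)
  significance_style <- match.arg(significance_style)
  stopifnot(font_size > 0, sig_bar_spacing > 0, width > 0, height > 0, dpi > 0)
  structure(list(plot_type = plot_type, scale = scale, font_size = font_size,
                 palette = palette, significance_style = significance_style,
                 sig_bar_spacing = sig_bar_spacing, width = width,
                 height = height, dpi = dpi),
            class = "plot_config")
}

sig_bar_data <- function(stat, groups, y_max, step) {
  if (is.null(stat)) return(NULL)
  cmp <- stat$comparisons
  show <- if (grepl("^p", cmp$label[1] %||% "")) rep(TRUE, nrow(cmp)) else cmp$significant
  show[is.na(show)] <- FALSE
  cmp <- cmp[show, ]
  if (nrow(cmp) == 0L) return(NULL)
  cmp$x1 <- match(cmp$group_a, groups)
  cmp$x2 <- match(cmp$group_b, groups)
  cmp <- cmp[order(abs(cmp$x2 - cmp$x1)), ]
  cmp$y <- y_max + step * seq_len(nrow(cmp))
  cmp
}

#' Expression plot for one gene, with significance annotations
#'
#' Renders the chosen plot type on the chosen display scale, draws
#' significance bars (significant comparisons only when annotating with
#' asterisks; all tested comparisons when annotating with p-values), and
#' lists the statistical tests performed in the caption. Means and standard
#' deviations shown on the plot are those of the displayed values.
#'
#' @param expr an `expression_table`.
#' @param gene gene of interest to plot.
#' @param stat the gene's `stats_result` (or `NULL` for a data-only plot).
#' @param cfg a [plot_config()].
#' @return a ggplot object.
#' @export
plot_expression <- function(expr, gene, stat = NULL, cfg = plot_config()) {
  stopifnot(inherits(expr, "expression_table"))
  d <- expr[expr$gene == gene, ]
  if (nrow(d) == 0L) stop("no expression values for gene ", gene, call. = FALSE)
  d$y <- if (cfg$scale == "log2") d$log2_norm_expr else d$norm_expr
  groups <- unique(d$group)
  d$group_f <- factor(d$group, levels = groups)
  ylab <- if (cfg$scale == "log2") "log2 relative expression" else "relative expression"

  summ <- dplyr::summarise(dplyr::group_by(d, .data$group_f),
                           mean = mean(.data$y), sd = stats::sd(.data$y),
                           .groups = "drop")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group_f, y = .data$y,
                                       colour = .data$group_f,
                                       fill = .data$group_f))
  p <- switch(cfg$plot_type,
    dots_all = p +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 2, show.legend = FALSE),
    dots_mean_sd = p +
      ggplot2::geom_point(data = summ, ggplot2::aes(y = .data$mean), size = 3,
                          show.legend = FALSE) +
      ggplot2::geom_errorbar(data = summ,
                             ggplot2::aes(y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             width = 0.2, show.legend = FALSE),
    bars_mean_sd = ggplot2::ggplot(summ,
        ggplot2::aes(x = .data$group_f, y = .data$mean, fill = .data$group_f)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             width = 0.2, show.legend = FALSE),
    box = p + ggplot2::geom_boxplot(alpha = 0.4, show.legend = FALSE)
  )

  caption <- if (!is.null(stat)) {
    parts <- c(if (!is.null(stat$omnibus)) stat$omnibus$test,
               unique(stat$comparisons$test),
               if (stat$plan$adjustment != "none")
                 paste0(stat$plan$adjustment, " adjustment"))
    paste("Tests:", paste(parts, collapse = "; "),
          sprintf("(on log2 values, alpha = %g)", stat$alpha))
  } else NULL

  y_all <- c(d$y, summ$mean + ifelse(is.na(summ$sd), 0, summ$sd))
  rng <- range(y_all)
  step <- cfg$sig_bar_spacing * max(diff(rng), 1e-9)
  bars <- sig_bar_data(stat, groups, rng[2], step)
  if (!is.null(bars)) {
    p <- p +
      ggplot2::annotate("segment", x = bars$x1, xend = bars$x2,
                        y = bars$y, yend = bars$y, linewidth = 0.4) +
      ggplot2::annotate("text", x = (bars$x1 + bars$x2) / 2,
                        y = bars$y + 0.25 * step, label = bars$label,
                        size = cfg$font_size / 3.5, vjust = 0)
  }

  p +
    ggplot2::scale_colour_brewer(palette = cfg$palette) +
    ggplot2::scale_fill_brewer(palette = cfg$palette) +
    ggplot2::labs(title = gene, x = NULL, y = ylab, caption = caption) +
    ggplot2::theme_classic(base_size = cfg$font_size) +
    ggplot2::theme(plot.caption = ggplot2::element_text(hjust = 0))
}

#' Diagnostic standard-curve plot for one amplicon
#'
#' Cq against log10(dilution factor) with the fitted parallel per-replicate
#' lines, annotated with the shared slope, the efficiency and R-squared.
#' Flagged outlier wells are drawn as crossed red markers.
#'
#' @param fit an `amplicon_fit`.
#' @param cfg a [plot_config()] (font size only).
#' @return a ggplot object.
#' @export
plot_standard_curve <- function(fit, cfg = plot_config()) {
  stopifnot(inherits(fit, "amplicon_fit"))
  w <- fit$wells
  w$replicate <- factor(w$sample, levels = names(fit$intercepts))
  lines <- tibble::tibble(
    replicate = factor(names(fit$intercepts), levels = names(fit$intercepts)),
    intercept = unname(fit$intercepts), slope = fit$slope_b
  )
  ann <- sprintf("slope = %.3f  E = %.3f  R² = %.4f",
                 fit$slope_b, fit$efficiency, fit$r_squared)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$log10d, y = .data$cq,
                                  colour = .data$replicate)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$replicate),
                         linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = w[w$outlier, ], shape = 4, size = 4,
                        colour = "red", stroke = 1.2) +
    ggplot2::labs(title = fit$amplicon, subtitle = ann,
                  x = "log10(dilution factor)", y = "Cq (cycles)",
                  colour = "replicate") +
    ggplot2::theme_classic(base_size = cfg$font_size)
}

#' Diagnostic Cq-Cq plot of a gene of interest against a reference gene
#'
#' @param ds the cq-mode dataset (supplies the paired well Cq values).
#' @param cq a [cqcq_fit()].
#' @param cfg a [plot_config()].
#' @return a ggplot object.
#' @export
plot_cqcq <- function(ds, cq, cfg = plot_config()) {
  stopifnot(inherits(ds, "qpcr_dataset"), inherits(cq, "cqcq_fit"))
  w <- ds$wells
  gw <- w[w$amplicon == cq$goi, c("sample", "dilution", "cq")]
  rw <- w[w$amplicon == cq$rg, c("sample", "dilution", "cq")]
  names(gw)[3] <- "cq_goi"
  names(rw)[3] <- "cq_rg"
  d <- dplyr::inner_join(gw, rw, by = c("sample", "dilution"))
  d <- d[!is.na(d$cq_goi) & !is.na(d$cq_rg) & d$sample %in% names(cq$offsets), ]
  d$replicate <- factor(d$sample, levels = names(cq$offsets))
  lines <- tibble::tibble(
    replicate = factor(names(cq$offsets), levels = names(cq$offsets)),
    intercept = unname(cq$offsets), slope = cq$slope_ratio
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cq_rg, y = .data$cq_goi,
                                  colour = .data$replicate)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$replicate),
                         linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = paste0(cq$goi, " vs ", cq$rg),
                  subtitle = sprintf("slope ratio = %.4f", cq$slope_ratio),
                  x = paste0("Cq ", cq$rg, " (cycles)"),
                  y = paste0("Cq ", cq$goi, " (cycles)"),
                  colour = "replicate") +
    ggplot2::theme_classic(base_size = cfg$font_size)
}

#' Write all result tables and figures of an analysis
#'
#' Tables are written as point-decimal CSV. Expression figures go to one
#' multi-page PDF per plot type (one gene per page) and to one PNG per gene
#' in a per-plot-type subdirectory. File names start with the dataset name,
#' include the plot type, and carry a `log` marker when the display scale is
#' logarithmic.
#'
#' @param outdir output directory (created if needed).
#' @param dataset_name name prefix for every output file.
#' @param expr an `expression_table`.
#' @param fits optional named list of `amplicon_fit` objects.
#' @param stats optional list from [run_tests()].
#' @param ds optional dataset (enables Cq-Cq diagnostic pages).
#' @param cfg a [plot_config()].
#' @return character vector of files written, invisibly.
#' @export
export_all <- function(outdir, dataset_name, expr, fits = NULL, stats = NULL,
                       ds = NULL, cfg = plot_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir, call. = FALSE)
  written <- character()
  out <- function(...) file.path(outdir, paste0(dataset_name, "_", ...))

  expr_df <- as.data.frame(expr)
  written <- c(written, write_table(expr_df, out("expression.csv")))
  rq <- attr(expr, "rq")
  if (!is.null(rq)) {
    written <- c(written, write_table(rq, out("relative_quantities.csv")))
  }
  if (!is.null(fits)) {
    written <- c(written, write_table(fits_summary(fits), out("standard_curves.csv")))
  }
  if (!is.null(stats) && length(stats) > 0L) {
    written <- c(written, write_table(stats_table(stats), out("stats.csv")))
  }

  log_tag <- if (cfg$scale == "log2") "_log" else ""
  genes <- unique(expr$gene)
  plots <- lapply(genes, function(g) {
    plot_expression(expr, g, stat = stats[[g]], cfg = cfg)
  })

  pdf_path <- out(cfg$plot_type, log_tag, ".pdf")
  grDevices::pdf(pdf_path, width = cfg$width, height = cfg$height)
  for (p in plots) print(p)
  grDevices::dev.off()
  written <- c(written, pdf_path)

  png_dir <- file.path(outdir, paste0(cfg$plot_type, log_tag))
  dir.create(png_dir, showWarnings = FALSE)
  for (i in seq_along(genes)) {
    png_path <- file.path(png_dir, paste0(dataset_name, "_", genes[i], "_",
                                          cfg$plot_type, log_tag, ".png"))
    grDevices::png(png_path, width = cfg$width, height = cfg$height,
                   units = "in", res = cfg$dpi)
    print(plots[[i]])
    grDevices::dev.off()
    written <- c(written, png_path)
  }

  if (!is.null(fits)) {
    diag_path <- out("diagnostics.pdf")
    grDevices::pdf(diag_path, width = cfg$width, height = cfg$height)
    for (f in fits) print(plot_standard_curve(f, cfg))
    if (!is.null(ds) && ds$mode == "cq") {
      for (g in genes_of_interest(ds)) {
        for (r in ds$reference_genes) {
          print(plot_cqcq(ds, cqcq_fit(fits[[g]], fits[[r]]), cfg))
        }
      }
    }
    grDevices::dev.off()
    written <- c(written, diag_path)
  }
  invisible(written)
}
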