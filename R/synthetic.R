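#' Ground truth for a simulated dilution-replicate experiment
#'
#' Encodes everything the simulator needs: true per-amplicon amplification
#' efficiencies, true relative template quantities per replicate, the
#' dilution series, Cq noise, and (optionally) a rate of missing
#' reference-gene wells. Defaults describe a typical two-group experiment
#' with fivefold serial dilutions (factors 1, 5, 25) and three biological
#' replicates per group.
#'
#' `quantities` sets the true relative template quantity of each (group,
#' amplicon); it may be a single number, a vector named by group (applied to
#' every gene of interest in that group), or a list named by group of vectors
#' named by amplicon. Reference-gene quantities default to 1 in every group
#' (stable expression).
#'
#' @param groups character, group names (no underscores needed; replicate
#'   suffixes are appended automatically).
#' @param n_replicates biological replicates per group (recycled over groups).
#' @param reference_genes,target_genes amplicon names.
#' @param efficiencies true efficiencies in (1, 2], single value or named by
#'   amplicon.
#' @param quantities true relative quantities (> 0), see Details.
#' @param dilution_factors positive dilution factors, default `c(1, 5, 25)`.
#' @param noise_sd standard deviation of i.i.d. Gaussian Cq noise, in cycles.
#' @param baseline_cq Cq of a quantity-1 template at dilution 1, single value
#'   or named by amplicon.
#' @param missing_rate fraction of reference-gene wells blanked at random.
#' @param paired if `TRUE`, replicates with the same index across groups share
#'   a pair identifier.
#' @param seed integer seed making the simulation reproducible.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(groups = c("A", "B"),
                         n_replicates = 3,
                         reference_genes = "RG1",
                         target_genes = "GOI1",
                         efficiencies = 2,
                         quantities = 1,
                         dilution_factors = c(1, 5, 25),
                         noise_sd = 0.2,
                         baseline_cq = 22,
                         missing_rate = 0,
                         paired = FALSE,
                         seed = 1L) {
  amplicons <- c(reference_genes, target_genes)
  expand_by_amplicon <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(amplicons)), amplicons)
    }
    if (!all(amplicons %in% names(x))) {
      stop(what, " must be a single value or named for every amplicon", call. = FALSE)
    }
    x[amplicons]
  }
  eff <- expand_by_amplicon(efficiencies, "efficiencies")
  base <- expand_by_amplicon(baseline_cq, "baseline_cq")
  if (any(eff <= 1 | eff > 2)) {
    stop("true efficiencies must lie in (1, 2]", call. = FALSE)
  }
  if (any(dilution_factors <= 0)) stop("dilution factors must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  n_replicates <- rep(n_replicates, length.out = length(groups))

  q_of <- function(g, a) {
    q <- 1
    if (is.list(quantities)) {
      if (!is.null(quantities[[g]])) {
        qg <- quantities[[g]]
        q <- if (length(qg) == 1L && is.null(names(qg))) {
          if (a %in% reference_genes) 1 else unname(qg)
        } else if (!is.null(names(qg)) && a %in% names(qg)) qg[[a]] else 1
      }
    } else if (!is.null(names(quantities))) {
      if (g %in% names(quantities) && !(a %in% reference_genes)) q <- quantities[[g]]
    } else {
      q <- if (a %in% reference_genes) 1 else quantities
    }
    q
  }
  qtab <- tidyr::expand_grid(
    group = groups, amplicon = amplicons
  )
  qtab$q_true <- mapply(q_of, qtab$group, qtab$amplicon)
  if (any(qtab$q_true <= 0)) stop("true quantities must be positive", call. = FALSE)

  structure(list(
    groups = groups, n_replicates = n_replicates,
    reference_genes = reference_genes, target_genes = target_genes,
    amplicons = amplicons,
    efficiencies = eff, quantities = qtab,
    dilution_factors = dilution_factors, noise_sd = noise_sd,
    baseline_cq = base, missing_rate = missing_rate,
    paired = paired, seed = as.integer(seed)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$groups), " groups x ",
      paste(x$n_replicates, collapse = "/"), " replicates; amplicons: ",
      paste(sprintf("%s (E=%.3g)", x$amplicons, x$efficiencies), collapse = ", "),
      "\n  dilutions ", paste(x$dilution_factors, collapse = "/"),
      ", noise_sd ", x$noise_sd, ", missing_rate ", x$missing_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a dilution-replicate qPCR dataset with known ground truth
#'
#' Each well's quantification cycle follows the exponential-amplification
#' model: a template at relative quantity Q, diluted by factor D and amplified
#' with efficiency E, crosses the threshold at
#' `Cq = baseline - log10(Q)/log10(E) + log10(D)/log10(E)` cycles, plus
#' i.i.d. Gaussian noise. With zero noise the three wells of a replicate lie
#' exactly on a line in log10(D) with slope `1/log10(E)`. Missing wells are
#' injected completely at random, and only into reference-gene columns,
#' mirroring the scope of the imputation stage.
#'
#' @param gt a [ground_truth()] object.
#' @return list with elements `dataset` (a cq-mode `qpcr_dataset`) and
#'   `truth` (tibble of per-replicate true quantities, efficiencies and
#'   expected normalized expression per gene of interest).
#' @export
#' @examples
#' sim <- simulate_dilrep(ground_truth(noise_sd = 0, seed = 42))
#' sim$dataset
simulate_dilrep <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  reps <- do.call(rbind, lapply(seq_along(gt$groups), function(i) {
    data.frame(group = gt$groups[i], replicate_id = as.character(seq_len(gt$n_replicates[i])),
               stringsAsFactors = FALSE)
  }))
  reps$sample <- paste0(reps$group, "_", reps$replicate_id)
  reps$pair_id <- if (gt$paired) reps$replicate_id else NA_character_

  grid <- tidyr::expand_grid(
    sample = reps$sample,
    dilution = gt$dilution_factors,
    amplicon = gt$amplicons
  )
  grid <- dplyr::left_join(grid, tibble::as_tibble(reps), by = "sample")
  grid <- dplyr::left_join(grid, gt$quantities, by = c("group", "amplicon"))
  log_e <- log10(gt$efficiencies)[grid$amplicon]
  cq0 <- gt$baseline_cq[grid$amplicon] -
    log10(grid$q_true) / log_e + log10(grid$dilution) / log_e

  withr::with_seed(gt$seed, {
    noise <- if (gt$noise_sd > 0) stats::rnorm(nrow(grid), 0, gt$noise_sd) else 0
    cq <- cq0 + noise
    if (gt$missing_rate > 0) {
      is_rg <- grid$amplicon %in% gt$reference_genes
      blank <- is_rg & stats::runif(nrow(grid)) < gt$missing_rate
      cq[blank] <- NA_real_
    }
  })

  wells <- tibble::tibble(
    sample = grid$sample, group = grid$group, replicate_id = grid$replicate_id,
    pair_id = grid$pair_id, dilution = grid$dilution,
    amplicon = grid$amplicon, cq = unname(cq)
  )
  ds <- new_qpcr_dataset(wells, gt$amplicons, gt$reference_genes, mode = "cq",
                         pairs_present = gt$paired)

  truth <- dplyr::distinct(grid[c("sample", "group", "replicate_id", "amplicon", "q_true")])
  truth$efficiency <- unname(gt$efficiencies[truth$amplicon])
  # expected normalized expression: Q_goi / geomean(Q_rg), rescaled so the
  # first group's geometric mean is 1 (matching the pipeline's convention)
  nf <- tapply(truth$q_true[truth$amplicon %in% gt$reference_genes],
               truth$sample[truth$amplicon %in% gt$reference_genes],
               geometric_mean)
  goi_rows <- truth$amplicon %in% gt$target_genes
  expected <- truth[goi_rows, ]
  expected$norm_expr_true <- unname(expected$q_true / as.numeric(nf[expected$sample]))
  ref_group <- gt$groups[1]
  expected <- do.call(rbind, lapply(split(expected, expected$amplicon), function(e) {
    e$norm_expr_true <- e$norm_expr_true /
      geometric_mean(e$norm_expr_true[e$group == ref_group])
    e
  }))
  rownames(expected) <- NULL
  expected$q_true <- unname(expected$q_true)
  expected$norm_expr_true <- unname(expected$norm_expr_true)

  list(dataset = ds, truth = tibble::as_tibble(expected))
}

#' Write the ground-truth sidecar of a simulation
#'
#' @param sim result of [simulate_dilrep()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  write_table(sim$truth, path)
}
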