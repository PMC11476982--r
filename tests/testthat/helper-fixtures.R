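# shared fixtures: small deterministic datasets built in code

# two-group, two-amplicon noiseless dataset with a known halving in group B
noiseless_halving <- function(n_replicates = 3, paired = FALSE) {
  simulate_dilrep(ground_truth(
    groups = c("A", "B"), n_replicates = n_replicates,
    reference_genes = "RG1", target_genes = "GOI1",
    efficiencies = 2, quantities = c(B = 0.5),
    noise_sd = 0, paired = paired, seed = 11L
  ))
}

# a ground truth with randomized efficiencies/quantities for property tests
random_ground_truth <- function(seed, n_groups = 2, n_replicates = 3,
                                n_rg = 1, n_goi = 1, noise_sd = 0.2,
                                missing_rate = 0) {
  withr::with_seed(seed, {
    groups <- LETTERS[seq_len(n_groups)]
    rg <- paste0("RG", seq_len(n_rg))
    goi <- paste0("GOI", seq_len(n_goi))
    amps <- c(rg, goi)
    ground_truth(
      groups = groups, n_replicates = n_replicates,
      reference_genes = rg, target_genes = goi,
      efficiencies = stats::setNames(stats::runif(length(amps), 1.7, 2), amps),
      quantities = stats::setNames(
        lapply(groups, function(g) stats::setNames(stats::runif(length(amps), 0.2, 5), amps)),
        groups),
      baseline_cq = stats::setNames(stats::runif(length(amps), 18, 26), amps),
      noise_sd = noise_sd, missing_rate = missing_rate,
      seed = sample.int(1e6, 1)
    )
  })
}

# expression table built directly from per-replicate linear values
expr_from_values <- function(values_by_group, gene = "G1", pair_ids = NULL) {
  rows <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(sample = paste0(g, "_", seq_along(v)), group = g,
               replicate_id = as.character(seq_along(v)),
               pair_id = if (is.null(pair_ids)) NA_character_ else pair_ids[[g]],
               amplicon = gene, value = v, stringsAsFactors = FALSE)
  }))
  ds <- new_qpcr_dataset(tibble::as_tibble(rows), gene, character(),
                         mode = "precalc")
  passthrough_precalc(ds)
}

# explicit normal-equations least squares on the indicator design matrix;
# independent oracle for the collinear fit
collinear_oracle <- function(wells) {
  w <- wells[!is.na(wells$cq), ]
  reps <- unique(w$sample)
  X <- cbind(sapply(reps, function(s) as.numeric(w$sample == s)),
             log10(w$dilution))
  colnames(X) <- c(reps, "slope")
  beta <- solve(crossprod(X), crossprod(X, w$cq))
  list(intercepts = stats::setNames(beta[seq_along(reps), 1], reps),
       slope = unname(beta[length(reps) + 1L, 1]))
}
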