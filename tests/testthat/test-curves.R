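test_that("noiseless data recover slope, efficiency and R^2 exactly", {
  sim <- noiseless_halving()
  fit <- fit_collinear(sim$dataset, "GOI1")
  expect_equal(fit$slope_b, 1 / log10(2), tolerance = 1e-9)   # 3.321928...
  expect_equal(fit$efficiency, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_wells_used, 18L)
  # group B was simulated with half the template: intercepts one cycle apart
  expect_equal(unname(fit$intercepts[["B_1"]] - fit$intercepts[["A_1"]]),
               1, tolerance = 1e-9)
})

test_that("collinear fit matches explicit normal-equations least squares", {
  for (seed in 1:20) {
    gt <- random_ground_truth(seed, n_groups = sample(2:4, 1), n_rg = 1, n_goi = 1)
    ds <- simulate_dilrep(gt)$dataset
    for (a in gt$amplicons) {
      fit <- fit_collinear(ds, a)
      oracle <- collinear_oracle(ds$wells[ds$wells$amplicon == a, ])
      expect_equal(fit$slope_b, oracle$slope, tolerance = 1e-10)
      expect_equal(fit$intercepts, oracle$intercepts[names(fit$intercepts)],
                   tolerance = 1e-10)
    }
  }
})

test_that("noisy efficiency estimates concentrate around the truth", {
  errs <- vapply(1:60, function(seed) {
    gt <- ground_truth(groups = c("A", "B", "C"), n_replicates = 3,
                       efficiencies = 1.9, noise_sd = 0.2, seed = seed)
    fit <- fit_collinear(simulate_dilrep(gt)$dataset, "GOI1")
    abs(fit$efficiency - 1.9)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("slope precision improves with the number of replicates", {
  se_for <- function(n_reps) {
    median(vapply(1:30, function(seed) {
      gt <- ground_truth(groups = "A", n_replicates = n_reps,
                         noise_sd = 0.2, seed = seed)
      fit_collinear(simulate_dilrep(gt)$dataset, "GOI1")$slope_se
    }, numeric(1)))
  }
  expect_gt(se_for(3), se_for(9))
})

test_that("rank-deficient and ineligible designs are rejected", {
  sim <- noiseless_halving()
  ds <- sim$dataset
  # keep only dilution 1 -> slope unidentifiable
  ds1 <- ds
  ds1$wells$cq[ds1$wells$dilution != 1 & ds1$wells$amplicon == "GOI1"] <- NA
  expect_error(suppressWarnings(fit_collinear(ds1, "GOI1")), "fit-eligible|rank")
  expect_error(fit_collinear(ds, "nope"), "unknown amplicon")
  expect_error(fit_collinear(passthrough_ds <- local({
    f <- tempfile(fileext = ".csv")
    writeLines(c("Replicates,Pairs,G1", "A_1,,2", "A_2,,1"), f)
    read_precalc_table(f)
  }), "G1"), "cq-mode")
})

test_that("replicates with a single observed dilution are dropped with a warning", {
  sim <- noiseless_halving()
  ds <- sim$dataset
  drop <- ds$wells$amplicon == "GOI1" & ds$wells$sample == "B_3" &
    ds$wells$dilution > 1
  ds$wells$cq[drop] <- NA
  expect_warning(fit <- fit_collinear(ds, "GOI1"), "excluded")
  expect_false("B_3" %in% names(fit$intercepts))
  expect_equal(fit$efficiency, 2, tolerance = 1e-9)
})

test_that("an injected aberrant well is the only one flagged", {
  sim <- simulate_dilrep(ground_truth(
    groups = c("A", "B"), n_replicates = 4, noise_sd = 0.05, seed = 21L
  ))
  ds <- sim$dataset
  hit <- which(ds$wells$amplicon == "GOI1" & ds$wells$sample == "A_2" &
                 ds$wells$dilution == 5)
  ds$wells$cq[hit] <- ds$wells$cq[hit] + 5
  fit <- flag_outliers(suppressWarnings(fit_collinear(ds, "GOI1")))
  flagged <- fit$wells[fit$wells$outlier, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$sample, "A_2")
  expect_equal(flagged$dilution, 5)

  clean <- flag_outliers(fit_collinear(sim$dataset, "GOI1"))
  expect_equal(sum(clean$wells$outlier), 0L)
  # strictly noiseless data have all-zero residuals and must never flag
  exact <- flag_outliers(fit_collinear(noiseless_halving()$dataset, "GOI1"))
  expect_equal(sum(exact$wells$outlier), 0L)
  expect_equal(sum(flag_outliers(fit, threshold = Inf)$wells$outlier), 0L)
})

test_that("refitting without flagged wells restores the clean estimate, once", {
  sim <- noiseless_halving(n_replicates = 4)
  ds <- sim$dataset
  hit <- which(ds$wells$amplicon == "GOI1" & ds$wells$sample == "A_1" &
                 ds$wells$dilution == 25)
  ds$wells$cq[hit] <- ds$wells$cq[hit] + 4
  fit <- flag_outliers(suppressWarnings(fit_collinear(ds, "GOI1")))
  expect_equal(sum(fit$wells$outlier), 1L)
  refit <- refit_without_outliers(fit, ds)
  expect_equal(refit$efficiency, 2, tolerance = 1e-9)
  refit$wells$outlier[1] <- TRUE
  expect_error(refit_without_outliers(refit, ds), "at most once")
})

test_that("flagging requires residual degrees of freedom", {
  sim <- simulate_dilrep(ground_truth(
    groups = "A", n_replicates = 1, noise_sd = 0.1, seed = 2L
  ))
  fit <- fit_collinear(sim$dataset, "GOI1")  # 3 wells, 2 params -> df = 1
  expect_warning(out <- flag_outliers(fit), "degrees of freedom")
  expect_equal(sum(out$wells$outlier), 0L)
})

test_that("Cq-Cq lines combine the two collinear fits", {
  # GOI at perfect doubling, RG built to have slope exactly 3.5
  e_rg <- 10^(1 / 3.5)
  sim <- simulate_dilrep(ground_truth(
    groups = c("A", "B"), n_replicates = 3,
    efficiencies = c(RG1 = e_rg, GOI1 = 2), quantities = c(B = 2),
    noise_sd = 0, seed = 3L
  ))
  fits <- fit_all_amplicons(sim$dataset)
  cq <- cqcq_fit(fits$GOI1, fits$RG1)
  expect_equal(cq$slope_ratio, (1 / log10(2)) / 3.5, tolerance = 1e-9)
  expect_equal(cq$slope_ratio, 0.949122, tolerance = 1e-6)

  # replicates within a group share normalized expression -> equal offsets
  offs <- cq$offsets
  expect_equal(unname(offs[["A_1"]]), unname(offs[["A_2"]]), tolerance = 1e-9)
  expect_equal(unname(offs[["B_1"]]), unname(offs[["B_3"]]), tolerance = 1e-9)

  # same efficiency on both sides: ratio 1
  sim2 <- noiseless_halving()
  f2 <- fit_all_amplicons(sim2$dataset)
  expect_equal(cqcq_fit(f2$GOI1, f2$RG1)$slope_ratio, 1, tolerance = 1e-9)
})

test_that("classical efficiency evaluates 10^(-1/slope) and needs 3 points", {
  conc <- c(1, 0.2, 0.04)
  expect_equal(classical_efficiency(conc, 20 - (1 / log10(2)) * log10(conc)),
               2, tolerance = 1e-9)
  expect_equal(classical_efficiency(conc, 20 - 3.5 * log10(conc)),
               1.930698, tolerance = 1e-6)
  expect_error(classical_efficiency(c(1, 0.2), c(20, 22)), "3 points")
  expect_error(classical_efficiency(c(1, 1, 1), c(20, 21, 22)), "identical")
})

test_that("classical and collinear conventions give the same efficiency", {
  sim <- noiseless_halving()
  fit <- fit_collinear(sim$dataset, "RG1")
  w <- sim$dataset$wells
  series <- w[w$amplicon == "RG1" & w$sample == "A_1", ]
  e_classical <- classical_efficiency(1 / series$dilution, series$cq)
  expect_equal(e_classical, 10^(1 / fit$slope_b), tolerance = 1e-9)
})
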