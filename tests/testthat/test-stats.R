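test_that("the test plan follows the family / group-count / comparison contract", {
  expect_equal(select_tests(2, stats_config("parametric"))$test, "Welch t-test")
  expect_equal(select_tests(2, stats_config("parametric", paired = TRUE))$test,
               "paired t-test")
  expect_equal(select_tests(4, stats_config("parametric", "all_to_one"))$test,
               "Dunnett many-to-one t-test")
  expect_equal(select_tests(4, stats_config("parametric", "all_pairs"))$test,
               "Tukey HSD")
  expect_equal(select_tests(2, stats_config("nonparametric"))$test,
               "Mann-Whitney U test")
  plan <- select_tests(4, stats_config("nonparametric", "all_pairs"))
  expect_equal(plan$omnibus, "Kruskal-Wallis test")
  expect_equal(plan$test, "Dunn post-hoc test")
  expect_equal(plan$adjustment, "Holm")
  sel <- stats_config("parametric", "selected_pairs", selected = list(c("A", "B")))
  expect_equal(select_tests(4, sel)$adjustment, "Holm")
  expect_error(select_tests(1, stats_config()), "two groups")
})

test_that("configuration invariants are enforced", {
  expect_error(stats_config(comparisons = "selected_pairs"), "non-empty")
  expect_error(stats_config(selected = list(c("A", "B"))), "selected_pairs")
  expect_error(stats_config(alpha = 0), "alpha")
  expect_error(stats_config("parametric", "selected_pairs",
                            selected = list("A")), "exactly two")
  cfg <- stats_config("parametric", "selected_pairs", selected = "A:B")
  expect_equal(cfg$selected, list(c("A", "B")))
})

test_that("a clear log2 shift is detected by both families", {
  withr::with_seed(31L, {
    a <- 2^rnorm(9, 0, 0.2)
    b <- 2^rnorm(9, 3, 0.2)
  })
  expr <- expr_from_values(list(A = a, B = b))
  for (fam in c("parametric", "nonparametric")) {
    res <- run_tests(expr, stats_config(fam))
    cmp <- res$G1$comparisons
    expect_true(cmp$significant)
    expect_equal(cmp$label, "***")
  }
})

test_that("identical data give p = 1 and no significance", {
  expr <- expr_from_values(list(A = c(2, 2, 2), B = c(2, 2, 2)))
  expect_warning(res <- run_tests(expr, stats_config()), "degenerate|constant")
  expect_equal(res$G1$comparisons$p_adjusted, 1)
  expect_false(res$G1$comparisons$significant)
})

test_that("perfectly separated constant groups are reported as significant", {
  # noiseless pipelines produce exactly constant groups with distinct means
  expr <- expr_from_values(list(A = c(2, 2, 2), B = c(1, 1, 1)))
  expect_warning(res <- run_tests(expr, stats_config("parametric")),
                 "separation")
  expect_equal(res$G1$comparisons$p_raw, 0)
  expect_true(res$G1$comparisons$significant)
})

test_that("tests are invariant to linear rescaling of expression", {
  withr::with_seed(32L, {
    vals <- list(A = 2^rnorm(6, 0, 0.5), B = 2^rnorm(6, 0.8, 0.5),
                 C = 2^rnorm(6, -0.4, 0.5))
  })
  scaled <- lapply(vals, function(v) v * 7.3)
  for (cfg in list(stats_config("parametric", "all_pairs"),
                   stats_config("nonparametric", "all_to_one"))) {
    p1 <- stats_table(run_tests(expr_from_values(vals), cfg))
    p2 <- stats_table(run_tests(expr_from_values(scaled), cfg))
    expect_equal(p1$p_raw, p2$p_raw, tolerance = 1e-9)
    expect_equal(p1$p_adjusted, p2$p_adjusted, tolerance = 1e-9)
  }
})

test_that("Dunn post-hoc z-tests match the hand-computed rank statistic", {
  # groups 1-3 / 4-6 / 7-9: mean ranks 2, 5, 8; Var0 = N(N+1)/12 = 7.5
  # z_AB = -3 / sqrt(7.5 * 2/3) = -1.3416408, z_AC = -2.6832816
  expr <- expr_from_values(list(A = 2^c(1, 2, 3), B = 2^c(4, 5, 6),
                                C = 2^c(7, 8, 9)))
  res <- run_tests(expr, stats_config("nonparametric", "all_pairs"))
  cmp <- res$G1$comparisons
  key <- paste(cmp$group_a, cmp$group_b)
  expect_equal(cmp$p_raw[key == "A B"], 2 * pnorm(-3 / sqrt(5)), tolerance = 1e-9)
  expect_equal(cmp$p_raw[key == "A C"], 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-9)
  expect_equal(cmp$p_raw[key == "B C"], 2 * pnorm(-3 / sqrt(5)), tolerance = 1e-9)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))
  expect_equal(res$G1$omnibus$test, "Kruskal-Wallis test")
  expect_equal(res$G1$omnibus$p,
               kruskal.test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$p.value,
               tolerance = 1e-9)
})

test_that("Dunnett comparisons run against the control group only", {
  withr::with_seed(33L, {
    vals <- list(Ctrl = 2^rnorm(6, 0, 0.3), T1 = 2^rnorm(6, 2, 0.3),
                 T2 = 2^rnorm(6, 0, 0.3), T3 = 2^rnorm(6, -2, 0.3))
  })
  res <- run_tests(expr_from_values(vals),
                   stats_config("parametric", "all_to_one"))
  cmp <- res$G1$comparisons
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$group_a == "Ctrl"))
  expect_true(all(cmp$test == "Dunnett many-to-one t-test"))
  # single-step adjusted p-values are computed by numerical integration with
  # tolerance ~1e-3; allow that much slack in the monotonicity check
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 2e-3))
  expect_true(cmp$significant[cmp$group_b == "T1"])
  expect_false(cmp$significant[cmp$group_b == "T2"])
})

test_that("selected pairs are tested with Holm adjustment, others skipped", {
  withr::with_seed(34L, {
    vals <- list(A = 2^rnorm(5), B = 2^rnorm(5, 3), C = 2^rnorm(5))
  })
  cfg <- stats_config("parametric", "selected_pairs",
                      selected = list(c("A", "B"), c("A", "C")))
  cmp <- run_tests(expr_from_values(vals), cfg)$G1$comparisons
  expect_equal(nrow(cmp), 2L)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 1e-12))
  expect_error(run_tests(expr_from_values(vals),
                         stats_config("parametric", "selected_pairs",
                                      selected = list(c("A", "Z")))),
               "not in the data")
})

test_that("paired tests use pair identifiers and fall back when incomplete", {
  withr::with_seed(35L, {
    base <- rnorm(8, 0, 0.3)
    shift <- 0.5 + rnorm(8, 0, 0.05)
  })
  vals <- list(A = 2^base, B = 2^(base + shift))
  ids <- list(A = as.character(1:8), B = as.character(1:8))
  expr <- expr_from_values(vals, pair_ids = ids)
  res <- run_tests(expr, stats_config("parametric", paired = TRUE))
  expect_equal(res$G1$comparisons$test, "paired t-test")
  # the shift is constant on log2 scale: a paired t-test is near-certain
  expect_true(res$G1$comparisons$significant)

  expr_nopairs <- expr_from_values(vals)
  expect_warning(res2 <- run_tests(expr_nopairs,
                                   stats_config("parametric", paired = TRUE)),
                 "pairing")
  expect_equal(unique(res2$G1$comparisons$test), "Welch t-test")
})

test_that("labels follow the asterisk thresholds and style switch", {
  withr::with_seed(36L, {
    vals <- list(A = 2^rnorm(9, 0, 0.2), B = 2^rnorm(9, 4, 0.2))
  })
  res <- run_tests(expr_from_values(vals), stats_config())
  expect_equal(res$G1$comparisons$label, "***")
  res_p <- run_tests(expr_from_values(vals),
                     stats_config(label_style = "p_values"))
  expect_match(res_p$G1$comparisons$label, "^p[<=]")
})

test_that("undersized groups are dropped and lone groups skip the gene", {
  expr <- expr_from_values(list(A = c(1, 2, 1.5), B = 3))
  expect_warning(res <- run_tests(expr, stats_config()), "fewer than 2")
  expect_length(res, 0L)
})
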