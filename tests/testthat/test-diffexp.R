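test_that("paired t-test matches the closed form and stats::t.test", {
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  # d = (1,2,3): t = 2 / (1 / sqrt(3)) = 2 sqrt(3); df = 2 two-sided p via
  # CDF(t) = 1/2 + t / (2 sqrt(2 + t^2))
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, 2 * (1 - (0.5 + 2 * sqrt(3) / (2 * sqrt(2 + 12)))),
    tolerance = 1e-10
  )
  expect_equal(round(res$t_stat, 4), 3.4641)
  expect_equal(round(res$p_value, 4), 0.0742)

  set.seed(101)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    scar <- rnorm(n)
    normal <- rnorm(n)
    ours <- paired_t_test(scar, normal)
    ref <- t.test(scar, normal, paired = TRUE)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance rows stay total", {
  x <- c(1, 2, 3)
  expect_equal(paired_t_test(x, x)$t_stat, 0)
  expect_equal(paired_t_test(x, x)$p_value, 1)
  up <- paired_t_test(x + 1, x)
  expect_equal(up$t_stat, Inf)
  expect_equal(up$p_value, 0)
  down <- paired_t_test(x - 1, x)
  expect_equal(down$t_stat, -Inf)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("BH adjustment reproduces hand-worked examples and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(202)
  for (i in 1:10) {
    p <- runif(50)
    q <- fdr_adjust(p)
    expect_true(all(q >= p)) # adjustment never decreases
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15)) # monotone in p
    qs <- fdr_adjust(p, method = "storey")
    expect_true(all(qs >= p - 1e-15))
    expect_true(all(qs <= q + 1e-15)) # pi0 <= 1 shrinks toward p
  }
})

test_that("differential_table composes the row test with joint FDR", {
  expr <- make_expr(matrix(c(5, 7, 4, 5), 1, 4), ids = "miR-0001")
  sheet <- make_sheet(2)
  de <- differential_table(expr, sheet)
  direct <- paired_t_test(c(5, 4), c(7, 5))
  expect_equal(de$t_stat, direct$t_stat)
  expect_equal(de$p_value, direct$p_value)
  expect_equal(de$q_value, direct$p_value) # m = 1
  expect_equal(de$mean_log2_diff, mean(c(5 - 7, 4 - 5)))
  expect_equal(de$fold_change, 2^de$mean_log2_diff)
  expect_equal(de$direction, "lowered")
})

test_that("swapping scar/normal labels negates t and preserves p", {
  sim <- simulate_mirna_dataset(sim_config(n_mirnas = 40, n_patients = 5, seed = 31))
  logged <- log2_transform(subtract_background(sim$expression, 50))
  de <- differential_table(logged, sim$samples)
  flipped <- sim$samples
  flipped$condition <- ifelse(flipped$condition == "scar", "normal", "scar")
  de2 <- differential_table(logged, flipped)
  both <- dplyr::inner_join(de, de2, by = "mirna_id", suffix = c("", ".flip"))
  expect_equal(both$t_stat, -both$t_stat.flip)
  expect_equal(both$p_value, both$p_value.flip)
})

test_that("FDR-significant miRNAs are always t-test-significant", {
  for (seed in 1:5) {
    sim <- simulate_mirna_dataset(sim_config(
      n_mirnas = 200, n_patients = 9, n_true_de = 20, seed = seed
    ))
    de <- differential_table(preprocess_expression(sim$expression, background = 50), sim$samples)
    expect_true(all(de$mirna_id[de$q_value <= 0.05] %in% de$mirna_id[de$p_value <= 0.05]))
  }
})

test_that("a strongly planted miRNA attains the smallest p-value", {
  sim <- simulate_mirna_dataset(sim_config(
    n_mirnas = 200, n_patients = 9, n_true_de = 1, frac_down = 0,
    effect_log2 = 3, noise_sd = 0.3, bias_amplitude = 0, background_level = 0,
    seed = 33
  ))
  de <- differential_table(log2_transform(sim$expression), sim$samples)
  expect_equal(de$mirna_id[1], sim$truth$mirna_id)
  expect_equal(de$direction[1], "elevated")
})

test_that("null data give a nominal-level rejection rate", {
  sim <- simulate_mirna_dataset(sim_config(
    n_mirnas = 2000, n_patients = 9, n_true_de = 0, bias_amplitude = 0,
    background_level = 0, seed = 34
  ))
  de <- differential_table(log2_transform(sim$expression), sim$samples)
  rate <- mean(de$p_value <= 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("incomplete pairing is a design error naming patients", {
  expr <- make_expr(matrix(rnorm(12), 2, 6))
  sheet <- make_sheet(3)
  sheet$condition[2] <- "scar" # P01 now has two scar arrays
  expect_error(differential_table(expr, sheet), "P01")
})
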