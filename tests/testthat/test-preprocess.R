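test_that("background subtraction is clamped arithmetic on a copy", {
  expr <- make_expr(matrix(c(100, 10, 50, 2), 2, 2))
  out <- subtract_background(expr, background = 20)
  expect_equal(out$A01, c(80, 1)) # 10 - 20 clamps to the floor
  expect_equal(out$A02, c(30, 1))
  expect_equal(subtract_background(expr, background = 0), expr) # identity
  out2 <- subtract_background(expr, background = 50, floor = 1)
  expect_equal(out2$A01[2], 1)
  # per-array background
  out3 <- subtract_background(expr, background = c(A01 = 10, A02 = 40))
  expect_equal(out3$A01, c(90, 1))
  expect_equal(out3$A02, c(10, 1))
  expect_error(subtract_background(expr, background = -5), "background")
})

test_that("log2 transform is exact on powers of two and total otherwise", {
  expr <- make_expr(matrix(c(8, 1, 2^10, 2^-3), 2, 2))
  out <- log2_transform(expr)
  expect_equal(out$A01, c(3, 0))
  expect_equal(out$A02, c(10, -3))
  bad <- make_expr(matrix(c(4, 0), 1, 2), ids = "miR-bad")
  expect_error(log2_transform(bad), "miR-bad.*A02")
})

test_that("lowess normalization leaves identical arrays untouched", {
  x <- rnorm(50, 8, 2)
  expr <- make_expr(cbind(x, x, x, x))
  out <- lowess_normalize(expr)
  expect_equal(as.matrix(out[, -1]), as.matrix(expr[, -1]), tolerance = 1e-8)
})

test_that("a global +1 log2 shift of one array is normalized away", {
  sim <- simulate_mirna_dataset(sim_config(
    n_mirnas = 500, n_patients = 9, n_true_de = 0, bias_amplitude = 0,
    background_level = 0, seed = 21
  ))
  logged <- log2_transform(sim$expression)
  m <- as.matrix(logged[, -1])
  m[, 1] <- m[, 1] + 1.0
  shifted <- make_expr(m, ids = logged$mirna_id, arrays = colnames(m))
  out <- lowess_normalize(shifted)
  om <- as.matrix(out[, -1])
  ref <- apply(om, 1, median)
  expect_lt(abs(median(om[, 1] - ref)), 0.05)
})

test_that("lowess normalization removes most of a planted intensity-dependent bias", {
  sim <- simulate_mirna_dataset(sim_config(
    n_mirnas = 500, n_patients = 9, n_true_de = 0, bias_amplitude = 0.5,
    background_level = 0, seed = 22
  ))
  logged <- log2_transform(sim$expression)
  curvature <- function(expr) {
    m <- as.matrix(expr[, -1])
    ref <- apply(m, 1, median)
    mean(vapply(seq_len(ncol(m)), function(j) {
      fit <- lowess((m[, j] + ref) / 2, m[, j] - ref, f = 0.3, iter = 3)
      mean(abs(fit$y))
    }, numeric(1)))
  }
  before <- curvature(logged)
  after <- curvature(lowess_normalize(logged))
  expect_lt(after, 0.2 * before)
})

test_that("re-normalizing is a small perturbation that keeps arrays centred", {
  # A second pass removes no further bias, only re-fits the smoother's own
  # noise wiggle; it must change values far less than the first pass and
  # leave every array's median M at zero.
  for (seed in 23:25) {
    sim <- simulate_mirna_dataset(sim_config(bias_amplitude = 0.5, seed = seed))
    logged <- log2_transform(subtract_background(sim$expression, background = 50))
    once <- lowess_normalize(logged)
    twice <- lowess_normalize(once)
    first_change <- max(abs(as.matrix(once[, -1]) - as.matrix(logged[, -1])))
    second_change <- max(abs(as.matrix(twice[, -1]) - as.matrix(once[, -1])))
    expect_lt(second_change, 0.5 * first_change)
    m <- as.matrix(twice[, -1])
    ref <- apply(m, 1, median)
    expect_lt(max(abs(apply(m - ref, 2, median))), 0.05)
  }
})

test_that("lowess normalization is idempotent in the low-noise limit", {
  # With vanishing measurement noise the fitted curve is the planted bias
  # itself, so a second application has (almost) nothing left to fit.
  sim <- simulate_mirna_dataset(sim_config(
    noise_sd = 0.02, patient_sd = 0, n_true_de = 0, bias_amplitude = 0.2,
    background_level = 0, seed = 23
  ))
  logged <- log2_transform(sim$expression)
  once <- lowess_normalize(logged)
  twice <- lowess_normalize(once)
  expect_lt(max(abs(as.matrix(twice[, -1]) - as.matrix(once[, -1]))), 0.01)
})

test_that("normalization never reorders or renames rows and columns", {
  sim <- simulate_mirna_dataset(sim_config(n_mirnas = 50, n_patients = 4, seed = 24))
  logged <- log2_transform(sim$expression)
  out <- lowess_normalize(logged)
  expect_identical(out$mirna_id, logged$mirna_id)
  expect_identical(names(out), names(logged))
})

test_that("detection filter keeps and counts rows by the stated rule", {
  m <- rbind(
    matrix(5, 7, 4), # detected everywhere
    matrix(0, 3, 4) # below threshold everywhere
  )
  expr <- make_expr(m)
  expect_message(out <- detection_filter(expr, min_signal = 1, min_fraction = 0.5), "removed 3")
  expect_equal(nrow(out), 7L)
  expect_equal(nrow(detection_filter(expr, min_signal = 1, min_fraction = 0)), 10L)
  # a row sitting at the background floor is removed when the threshold exceeds it
  floor_row <- make_expr(rbind(matrix(c(0, 0, 0, 0), 1), matrix(5, 1, 4)))
  expect_message(out2 <- detection_filter(floor_row, min_signal = 1))
  expect_equal(nrow(out2), 1L)
})

test_that("the composed preprocessing records provenance", {
  sim <- simulate_mirna_dataset(sim_config(n_mirnas = 100, n_patients = 4, seed = 25))
  out <- preprocess_expression(sim$expression, background = 50)
  prov <- attr(out, "provenance")
  expect_equal(prov$span, 0.3)
  expect_equal(prov$iterations, 3)
  expect_equal(prov$n_removed, 100 - nrow(out))
  expect_false(anyNA(as.matrix(out[, -1])))
})
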