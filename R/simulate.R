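#' Configuration for the paired-design miRNA microarray simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' reproduce the shape of the motivating study: 513 miRNAs measured on 9
#' patients, each contributing one hypertrophic-scar and one normal-skin
#' array, with most planted differential miRNAs lowered in scar tissue.
#'
#' @param n_mirnas Number of miRNA probes simulated.
#' @param n_patients Number of patients; each yields one scar and one normal
#'   array, so the matrix has `2 * n_patients` columns.
#' @param n_true_de Number of miRNAs planted with a nonzero scar effect.
#' @param frac_down Fraction of planted miRNAs whose expression is lowered in
#'   scar (negative log2 effect).
#' @param effect_log2 Absolute log2 fold change of every planted miRNA
#'   (scar minus normal).
#' @param baseline_mean,baseline_sd Mean and SD of the per-miRNA baseline
#'   log2 expression level.
#' @param patient_sd SD of the per-patient random effect (log2 scale); shared
#'   by both arrays of a patient, so it cancels in paired differences.
#' @param noise_sd Residual SD per measurement (log2 scale).
#' @param background_level Additive background on the raw intensity scale.
#' @param bias_amplitude Maximum |log2 distortion| of the smooth per-array
#'   intensity-dependent bias curve that lowess normalization must remove.
#' @param seed Integer seed; identical configurations give identical data.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_mirna_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_mirnas = 50, n_patients = 4, seed = 1)
sim_config <- function(n_mirnas = 513,
                       n_patients = 9,
                       n_true_de = 20,
                       frac_down = 0.75,
                       effect_log2 = 1.5,
                       baseline_mean = 9,
                       baseline_sd = 2,
                       patient_sd = 0.5,
                       noise_sd = 0.5,
                       background_level = 50,
                       bias_amplitude = 0.3,
                       seed = 1L) {
  check_number(n_mirnas, "n_mirnas", min = 1, integerish = TRUE)
  check_number(n_patients, "n_patients", min = 1, integerish = TRUE)
  check_number(n_true_de, "n_true_de", min = 0, max = n_mirnas, integerish = TRUE)
  check_number(frac_down, "frac_down", min = 0, max = 1)
  check_number(effect_log2, "effect_log2", min = 0)
  check_number(baseline_mean, "baseline_mean")
  check_number(baseline_sd, "baseline_sd", min = 0)
  check_number(patient_sd, "patient_sd", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(background_level, "background_level", min = 0)
  check_number(bias_amplitude, "bias_amplitude", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      n_mirnas = as.integer(n_mirnas), n_patients = as.integer(n_patients),
      n_true_de = as.integer(n_true_de), frac_down = frac_down,
      effect_log2 = effect_log2, baseline_mean = baseline_mean,
      baseline_sd = baseline_sd, patient_sd = patient_sd,
      noise_sd = noise_sd, background_level = background_level,
      bias_amplitude = bias_amplitude, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Run code under a private RNG stream keyed on `seed`, leaving the caller's
# RNG state untouched.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulate a paired scar/normal miRNA microarray dataset
#'
#' Generates raw intensities under an additive model on the log2 scale: per
#' miRNA baseline + per-patient random effect + planted condition effect +
#' Gaussian noise. The true level `L` is then distorted exactly as the
#' preprocessing pipeline assumes real scanners distort it: raw intensity
#' `(2^L + background_level) * 2^(f_a(L))`, where `f_a` is a smooth per-array
#' intensity-dependent bias curve bounded by `bias_amplitude` in absolute
#' log2 units.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `"mirna_sim"` with elements
#'   * `expression`: tibble, first column `mirna_id`, one column per array,
#'     raw non-negative intensities;
#'   * `samples`: tibble with `array_id`, `patient_id`,
#'     `condition` (`"scar"`/`"normal"`), one complete pair per patient;
#'   * `truth`: tibble with `mirna_id` and signed `log2_effect` for the
#'     planted differential miRNAs (zero rows when `n_true_de = 0`);
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sim <- simulate_mirna_dataset(sim_config(n_mirnas = 40, n_patients = 4))
#' dim(sim$expression)
simulate_mirna_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  with_private_seed(config$seed, {
    n_g <- config$n_mirnas
    n_p <- config$n_patients
    ids <- sprintf("miR-%04d", seq_len(n_g))
    patients <- sprintf("P%02d", seq_len(n_p))
    samples <- tibble::tibble(
      array_id = sprintf("A%02d", seq_len(2L * n_p)),
      patient_id = rep(patients, each = 2L),
      condition = rep(c("scar", "normal"), times = n_p)
    )

    mu <- rnorm(n_g, config$baseline_mean, config$baseline_sd)
    delta <- numeric(n_g)
    de_idx <- integer(0)
    if (config$n_true_de > 0) {
      de_idx <- sort(sample.int(n_g, config$n_true_de))
      n_down <- round(config$frac_down * config$n_true_de)
      signs <- rep(c(-1, 1), c(n_down, config$n_true_de - n_down))
      delta[de_idx] <- signs * config$effect_log2
    }
    b <- rnorm(n_p, 0, config$patient_sd)

    n_a <- 2L * n_p
    pat_of <- rep(seq_len(n_p), each = 2L)
    is_scar <- samples$condition == "scar"
    L <- matrix(mu, n_g, n_a) +
      matrix(b[pat_of], n_g, n_a, byrow = TRUE) +
      outer(delta, as.numeric(is_scar)) +
      matrix(rnorm(n_g * n_a, 0, config$noise_sd), n_g, n_a)

    # Smooth per-array bias: amplitude-bounded quadratic in the true level.
    u1 <- runif(n_a, -1, 1)
    u2 <- runif(n_a, -1, 1)
    half_range <- max(4 * config$baseline_sd, 1)
    z <- pmin(pmax((L - config$baseline_mean) / half_range, -1), 1)
    f <- config$bias_amplitude / 2 *
      (sweep(z, 2, u1, "*") + sweep(2 * z^2 - 1, 2, u2, "*"))

    raw <- (2^L + config$background_level) * 2^f
    colnames(raw) <- samples$array_id

    structure(
      list(
        expression = expr_tibble(raw, ids),
        samples = samples,
        truth = tibble::tibble(
          mirna_id = ids[de_idx],
          log2_effect = delta[de_idx]
        ),
        config = config
      ),
      class = "mirna_sim"
    )
  })
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated paired miRNA dataset: %d miRNAs x %d arrays (%d patients), %d planted effects, seed %d\n",
    nrow(x$expression), ncol(x$expression) - 1L,
    x$config$n_patients, nrow(x$truth), x$config$seed
  ))
  invisible(x)
}
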