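# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards (no hidden global side effects)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Default TAC noise coefficient
#'
#' The TAC noise model is zero-mean Gaussian with standard deviation
#' `alpha * sqrt(mean_frame_activity / frame_duration)`, the standard
#' frame-level approximation of reconstructed PET noise (variance
#' proportional to activity, inversely proportional to frame duration).
#' The default alpha = 0.2 (kBq^0.5 mL^-0.5 min^0.5) gives roughly 3%
#' noise on a late 5-min frame at 10 kBq/mL and roughly 7% at a 50 kBq/mL
#' bolus peak in a 10-s frame, typical of clinical whole-body
#' reconstructions.
#'
#' @return The default noise coefficient.
#' @export
default_noise_alpha <- function() 0.2

#' Simulate a noisy tissue time-activity curve
#'
#' Computes the continuous two-tissue compartment solution for `kp` (see
#' [model_tac()]), averages it over each acquisition frame, and adds
#' zero-mean Gaussian noise with SD `alpha * sqrt(mean / duration)` per
#' frame. `noise_alpha = 0` returns the noiseless frame averages.
#'
#' @param kp A [kinetic_params()].
#' @param inp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @param noise_alpha Noise coefficient; see [default_noise_alpha()].
#' @param seed Integer seed; the same seed gives identical output.
#' @return A [tac()].
#' @export
simulate_tac <- function(kp, inp, schedule, noise_alpha = default_noise_alpha(),
                         seed = 1) {
  y <- signal_frame_avg(kinetic_context(inp, schedule), kp)
  if (noise_alpha > 0) {
    sdv <- noise_alpha * sqrt(pmax(y, 0) / schedule$dur)
    y <- y + with_seed(seed, rnorm(length(y), 0, sdv))
  }
  tac(schedule$mid, schedule$dur, y, label = "simulated")
}

#' Simulate venous blood samples
#'
#' Draws measured whole-blood and total-plasma activities at the given
#' sampling times with multiplicative Gaussian noise (coefficient of
#' variation `noise_cv`, independent between the two measurements), and
#' measured parent fractions with additive Gaussian noise of SD `noise_cv`
#' clipped to `[0, 1]`.
#'
#' @param inp An [input_function()].
#' @param times Sampling times in minutes; default the seven clinical
#'   sampling times 2, 5, 10, 20, 40, 60 and 120 min.
#' @param noise_cv Measurement noise level; 0 gives exact values.
#' @param seed Integer seed.
#' @return A `blood_sample_table` data frame with columns `time_min`,
#'   `whole_blood`, `plasma`, `parent_fraction`.
#' @export
sample_blood <- function(inp, times = c(2, 5, 10, 20, 40, 60, 120),
                         noise_cv = 0.03, seed = 1) {
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("sampling times must be positive and increasing")
  n <- length(times)
  wb <- if_cwb(inp, times)
  pl <- wb * inp$p2wb_ratio
  pf <- parent_fraction(inp$pf_model, times)
  if (noise_cv > 0) {
    z <- with_seed(seed, rnorm(3 * n))
    wb <- wb * (1 + noise_cv * z[1:n])
    pl <- pl * (1 + noise_cv * z[(n + 1):(2 * n)])
    pf <- pmin(pmax(pf + noise_cv * z[(2 * n + 1):(3 * n)], 0), 1)
  }
  out <- data.frame(time_min = times, whole_blood = wb, plasma = pl,
                    parent_fraction = pf)
  class(out) <- c("blood_sample_table", "data.frame")
  out
}
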