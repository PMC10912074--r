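#' Kinetic parameters of the two-tissue compartment model
#'
#' Rate constants of the serial two-tissue compartment model: K1 (plasma to
#' free tissue compartment, mL cm^-3 min^-1), k2 (free tissue to plasma,
#' min^-1), k3 (free to bound, min^-1), k4 (bound to free, min^-1) and the
#' fractional blood volume vB. Irreversible trapping corresponds to k4 = 0.
#'
#' @param K1,k2,k3,k4 Non-negative rate constants.
#' @param vB Fractional blood volume in `[0, 1]`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  v <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(v)) || any(v < 0)) stop("rate constants must be finite and >= 0")
  if (vB > 1) stop("vB must be in [0, 1]")
  structure(as.list(v), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> K1=%.4g k2=%.4g k3=%.4g k4=%.4g vB=%.4g (Ki=%.4g)\n",
              x$K1, x$k2, x$k3, x$k4, x$vB, macro_ki(x)))
  invisible(x)
}

#' Net influx rate Ki
#'
#' Macro-parameter of the irreversible two-tissue compartment model,
#' Ki = K1 k3 / (k2 + k3); equals the asymptotic Patlak slope.
#'
#' @param kp A [kinetic_params()] (or list with K1, k2, k3).
#' @return Ki in mL cm^-3 min^-1; 0 when k2 + k3 = 0.
#' @export
macro_ki <- function(kp) {
  if (kp$k2 + kp$k3 == 0) return(0)
  kp$K1 * kp$k3 / (kp$k2 + kp$k3)
}

# Precompute everything about (input, schedule) that the forward model
# reuses across parameter evaluations: the merged knot grid (input knots
# within the scan plus all frame boundaries), per-segment linear pieces of
# Cp, the running integral I of Cp, the running integral of I (for exact
# frame averages of the theta = 0 convolution), frame boundary indices and
# frame-averaged whole blood.
kinetic_context <- function(inp, schedule) {
  t_end <- max(schedule$end)
  tk <- sort(unique(c(0, inp$t_knots[inp$t_knots < t_end + 1e-9],
                      schedule$start, schedule$end)))
  cp <- if_cp(inp, tk)
  cwb <- if_cwb(inp, tk)
  m <- length(tk)
  dt <- diff(tk)
  a <- cp[-m]
  b <- diff(cp) / dt
  I <- c(0, cumsum((cp[-m] + cp[-1]) / 2 * dt))
  # running integral of I: per segment, I_j*dt + a*dt^2/2 + b*dt^3/6
  II <- c(0, cumsum(I[-m] * dt + a * dt^2 / 2 + b * dt^3 / 6))
  cwb_cum <- c(0, cumsum((cwb[-m] + cwb[-1]) / 2 * dt))
  is <- match(round(schedule$start, 10), round(tk, 10))
  ie <- match(round(schedule$end, 10), round(tk, 10))
  if (anyNA(is) || anyNA(ie)) stop("internal: frame boundaries not on knot grid")
  list(tk = tk, dt = dt, a = a, b = b, I = I, II = II,
       is = is, ie = ie, dur = schedule$dur,
       avg_cwb = (cwb_cum[ie] - cwb_cum[is]) / schedule$dur,
       schedule = schedule)
}

# frame averages of F_theta(t) = int_0^t exp(-theta (t-s)) Cp(s) ds
frame_avg_conv <- function(ctx, theta) {
  if (theta < 1e-12) {
    (ctx$II[ctx$ie] - ctx$II[ctx$is]) / ctx$dur
  } else {
    Fk <- .cpp_conv_exp(theta, ctx$dt, ctx$a, ctx$b)
    ((ctx$I[ctx$ie] - ctx$I[ctx$is]) - (Fk[ctx$ie] - Fk[ctx$is])) /
      (theta * ctx$dur)
  }
}

# frame-averaged total tissue concentration C1 + C2 for given rates;
# closed-form bi-exponential convolution with the piecewise-linear Cp,
# frame averages exact. Degenerate (repeated) eigenvalues use the t*exp
# limit solution rather than failing.
tissue_frame_avg <- function(ctx, K1, k2, k3, k4) {
  if (K1 == 0) return(numeric(length(ctx$dur)))
  s <- k2 + k3 + k4
  if (s == 0) return(K1 * frame_avg_conv(ctx, 0))
  disc <- s^2 - 4 * k2 * k4
  sq <- sqrt(max(disc, 0))
  a1 <- (s - sq) / 2
  a2 <- (s + sq) / 2
  if ((a2 - a1) > 1e-7 * a2) {
    c1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
    c2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
    c1 * frame_avg_conv(ctx, a1) + c2 * frame_avg_conv(ctx, a2)
  } else {
    # repeated eigenvalue alpha = s/2: CT = K1 [ (k3 + k4 - a) H + F ]
    al <- s / 2
    Fk <- .cpp_conv_exp(al, ctx$dt, ctx$a, ctx$b)
    Hk <- .cpp_conv_texp(al, ctx$dt, ctx$a, ctx$b, Fk)
    intF <- (ctx$I[ctx$ie] - ctx$I[ctx$is]) - (Fk[ctx$ie] - Fk[ctx$is])
    avgF <- intF / (al * ctx$dur)
    avgH <- (intF / al - (Hk[ctx$ie] - Hk[ctx$is])) / (al * ctx$dur)
    K1 * ((k3 + k4 - al) * avgH + avgF)
  }
}

# frame-averaged measured PET signal
signal_frame_avg <- function(ctx, kp) {
  (1 - kp$vB) * tissue_frame_avg(ctx, kp$K1, kp$k2, kp$k3, kp$k4) +
    kp$vB * ctx$avg_cwb
}

#' Forward two-tissue compartment model
#'
#' Solves the two-tissue compartment system
#' dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2, dC2/dt = k3 C1 - k4 C2
#' by its closed-form bi-exponential convolution with the piecewise-linear
#' parent-plasma input (each linear segment integrated exactly), forms the
#' measured signal (1 - vB)(C1 + C2) + vB Cwb, and averages it exactly over
#' each acquisition frame. Repeated eigenvalues are handled by the analytic
#' t exp(-at) limit.
#'
#' @param kp A [kinetic_params()].
#' @param inp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @return A [tac()] of noiseless frame-averaged activity, kBq/mL.
#' @export
model_tac <- function(kp, inp, schedule) {
  ctx <- kinetic_context(inp, schedule)
  tac(schedule$mid, schedule$dur, signal_frame_avg(ctx, kp),
      label = "2TCM model")
}

#' Akaike information criterion for least-squares fits
#'
#' AIC = n log(RSS / n) + 2p, the usual kinetic-modeling convention for
#' fits by (weighted) least squares; no small-sample correction.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of fitted frames.
#' @param p Number of free parameters (n > p).
#' @return The AIC value; `-Inf` with a warning when `rss` is 0.
#' @export
aic <- function(rss, n, p) {
  if (n <= p) stop("need n > p")
  if (rss < 0) stop("rss must be >= 0")
  if (rss == 0) {
    warning("rss is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * p
}

# draw one random multi-start initialization within bounds:
# rates log-uniform on [max(lower, 1e-3), upper], vB uniform
random_start <- function(lower, upper) {
  k <- exp(runif(4, log(pmax(lower[1:4], 1e-3)), log(pmax(upper[1:4], 2e-3))))
  vB <- runif(1, lower[5], upper[5])
  c(k, vB)
}

#' Fit a two-tissue compartment model to a time-activity curve
#'
#' Bounded nonlinear weighted least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the reversible (k4 free) or irreversible (k4 = 0)
#' two-tissue compartment model. A multi-start strategy is used: the default
#' initialization plus `n_starts - 1` seeded log-uniform draws within the
#' bounds; the best converged solution is kept (ties broken by lower RSS,
#' then lower K1).
#'
#' @param tac_obj A [tac()] of measured frame activities.
#' @param inp An [input_function()].
#' @param schedule A [frame_schedule()]; if `NULL`, reconstructed from the
#'   TAC mid-times and durations.
#' @param mode `"reversible"` or `"irreversible"`.
#' @param weights Per-frame weights (default uniform); use
#'   `schedule$dur` for duration-proportional weighting.
#' @param init Optional named start vector (K1, k2, k3, k4, vB).
#' @param lower,upper Box bounds on (K1, k2, k3, k4, vB).
#' @param n_starts Number of starts (>= 1).
#' @param seed Seed for the random starts.
#' @return An object of class `fit_2tcm` with elements `params`
#'   ([kinetic_params()]), `ki`, `rss`, `aic`, `se` (approximate standard
#'   errors), `n_frames`, `n_free_params`, `mode`, `converged`, `fitted`.
#' @export
fit_2tcm <- function(tac_obj, inp, schedule = NULL,
                     mode = c("irreversible", "reversible"),
                     weights = NULL, init = NULL,
                     lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vB = 0),
                     upper = c(K1 = 2, k2 = 2, k3 = 2, k4 = 1, vB = 0.5),
                     n_starts = 5, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(schedule)) schedule <- schedule_from_tac(tac_obj)
  if (length(tac_obj$activity) != n_frames(schedule))
    stop("TAC and schedule are not aligned")
  y <- tac_obj$activity
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weights")
  sw <- sqrt(weights)
  ctx <- kinetic_context(inp, schedule)
  free <- if (mode == "irreversible") c(1, 2, 3, 5) else 1:5
  p_free <- length(free)
  if (n <= p_free) stop("need more frames than free parameters")

  default_init <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.01, vB = 0.05)
  if (!is.null(init)) default_init[names(init)] <- unlist(init)
  default_init <- pmin(pmax(default_init, lower), upper)

  expand_par <- function(par) {
    full <- numeric(5)   # k4 stays fixed at 0 in irreversible mode
    full[free] <- par
    list(K1 = full[1], k2 = full[2], k3 = full[3], k4 = full[4], vB = full[5])
  }
  resid_fn <- function(par) {
    sw * (y - signal_frame_avg(ctx, expand_par(par)))
  }

  starts <- list(default_init[free])
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (i in seq_len(n_starts - 1)) starts[[i + 1]] <- random_start(lower, upper)[free]
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old_seed, envir = globalenv())
  }

  best <- NULL
  best_attempt <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[free], upper = upper[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    ok <- fit$info %in% 1:4
    cand <- list(fit = fit, rss = rss, K1 = fit$par[1], converged = ok)
    if (is.null(best_attempt) || rss < best_attempt$rss) best_attempt <- cand
    if (!ok) next
    if (is.null(best) || rss < best$rss ||
        (rss == best$rss && fit$par[1] < best$K1)) best <- cand
  }
  if (is.null(best)) {
    if (is.null(best_attempt)) stop("non-convergence: all starts failed")
    warning("non-convergence: no start converged; returning best attempt")
    best <- best_attempt
  }

  par <- best$fit$par
  full <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vB = 0)
  full[free] <- par
  kp <- kinetic_params(full[["K1"]], full[["k2"]], full[["k3"]],
                       full[["k4"]], full[["vB"]])
  rss <- best$rss
  # approximate SEs from the Gauss-Newton hessian (2 J'J)
  se <- rep(NA_real_, p_free)
  covm <- tryCatch(solve(best$fit$hessian / 2) * rss / (n - p_free),
                   error = function(e) NULL)
  if (!is.null(covm)) {
    d <- diag(covm)
    se <- ifelse(d >= 0, sqrt(d), NA_real_)
  }
  names(se) <- names(full)[free]

  structure(list(
    params = kp, ki = macro_ki(kp), rss = rss, n_frames = n,
    n_free_params = p_free, aic = aic(rss, n, p_free), se = se,
    mode = mode, converged = best$converged, weights = weights,
    fitted = signal_frame_avg(ctx, expand_par(par))
  ), class = "fit_2tcm")
}

#' @export
print.fit_2tcm <- function(x, ...) {
  cat(sprintf("<fit_2tcm> %s: K1=%.4g k2=%.4g k3=%.4g k4=%.4g vB=%.4g\n",
              x$mode, x$params$K1, x$params$k2, x$params$k3, x$params$k4,
              x$params$vB))
  cat(sprintf("  Ki=%.4g  RSS=%.4g  AIC=%.2f  (n=%d, p=%d, converged=%s)\n",
              x$ki, x$rss, x$aic, x$n_frames, x$n_free_params, x$converged))
  invisible(x)
}

#' Compare reversible and irreversible fits by AIC
#'
#' Delta AIC = AIC(reversible) - AIC(irreversible). A positive delta favors
#' the irreversible model (lower AIC is better); |delta| > 2 is taken as a
#' significant difference between the models.
#'
#' @param fit_rev,fit_irr `fit_2tcm` objects for the reversible and
#'   irreversible model fitted to the same data.
#' @return An object of class `model_comparison` with `aic_reversible`,
#'   `aic_irreversible`, `delta_aic`, `preferred`, `significant`.
#' @export
compare_models <- function(fit_rev, fit_irr) {
  if (fit_rev$mode != "reversible" || fit_irr$mode != "irreversible")
    stop("arguments must be a reversible and an irreversible fit, in that order")
  if (fit_rev$n_frames != fit_irr$n_frames)
    stop("fits were not performed on the same number of frames")
  if (!isTRUE(all.equal(fit_rev$weights, fit_irr$weights)))
    stop("fits used different weights")
  delta <- fit_rev$aic - fit_irr$aic
  # on (near-)noiseless data both RSS values sit at solver-convergence
  # precision and their ratio is roundoff; treat such comparisons as ties
  if (!is.null(fit_irr$fitted) && !is.null(fit_rev$rss) &&
      !is.null(fit_irr$rss)) {
    scale <- sum(fit_irr$weights * fit_irr$fitted^2)
    if (is.finite(scale) && scale > 0 &&
        fit_rev$rss < 1e-9 * scale && fit_irr$rss < 1e-9 * scale)
      delta <- 0
  }
  structure(list(
    aic_reversible = fit_rev$aic, aic_irreversible = fit_irr$aic,
    delta_aic = delta,
    preferred = if (delta > 0) "irreversible" else "reversible",
    significant = abs(delta) > 2
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> dAIC = %.2f -> %s%s\n", x$delta_aic,
              x$preferred, if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Select a kinetic model from an AIC comparison
#'
#' Applies the decision rule used throughout the package: if the AIC
#' difference is significant (|delta AIC| > 2) the lower-AIC model is
#' selected; otherwise the parsimonious irreversible model (one fewer
#' parameter) is retained.
#'
#' @param cmp A [compare_models()] result.
#' @return `"irreversible"` or `"reversible"`.
#' @export
select_model <- function(cmp) {
  if (cmp$significant) cmp$preferred else "irreversible"
}
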