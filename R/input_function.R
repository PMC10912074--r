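#' Blood input function set
#'
#' Bundles the whole-blood activity curve Cwb(t), the (constant)
#' plasma-to-whole-blood activity ratio R, and a parent-fraction model pf(t)
#' into a single object from which the metabolite-corrected parent-plasma
#' input Cp(t) = Cwb(t) * R * pf(t) can be evaluated at arbitrary times.
#'
#' The whole-blood curve is represented piecewise-linearly on a knot grid
#' (dense for closed-form curves, frame mid-times for image-derived ones),
#' with constant extrapolation beyond the last knot. All time integrals of
#' Cp used downstream (compartment convolution, Patlak) are exact under this
#' piecewise-linear representation.
#'
#' @param t Knot times in minutes, starting at 0.
#' @param cwb Whole-blood activity at the knots, kBq/mL; `cwb[1]` must be 0.
#' @param p2wb_ratio Plasma-to-whole-blood activity ratio (dimensionless).
#' @param pf_model A [parent_fraction_model()], or `NULL` for pf = 1.
#' @param label Optional label.
#' @param refine Maximum knot spacing (min) of the internal grid used for
#'   integrals; sparse grids (e.g. frame mid-times) are subdivided so the
#'   piecewise-linear representation of Cp follows the smooth parent-fraction
#'   curve between whole-blood knots.
#' @param cp Optional explicit parent-plasma values at the knots (e.g. read
#'   back from a corrected-input file); when given, `p2wb_ratio`/`pf_model`
#'   are ignored and Cp is the piecewise-linear curve through these values.
#' @return An object of class `input_function`.
#' @export
input_function <- function(t, cwb, p2wb_ratio = 1, pf_model = NULL,
                           label = NULL, refine = 0.5, cp = NULL) {
  t <- as.numeric(t); cwb <- as.numeric(cwb)
  if (length(t) < 2L || length(t) != length(cwb))
    stop("need >= 2 knots with matching activity values")
  if (t[1] != 0) stop("knot grid must start at t = 0")
  if (any(diff(t) <= 0)) stop("knot times must be strictly increasing")
  if (cwb[1] != 0) stop("whole-blood activity must be 0 at t = 0")
  if (any(cwb < 0)) stop("invalid-parameters: whole-blood curve is negative")
  if (p2wb_ratio <= 0) stop("p2wb_ratio must be positive")
  cp_explicit <- !is.null(cp)
  if (cp_explicit) {
    cp <- as.numeric(cp)
    if (length(cp) != length(t) || any(cp < 0) || cp[1] != 0)
      stop("explicit cp must match the knots, be >= 0 and start at 0")
    p2wb_ratio <- 1
    pf_model <- NULL
  }
  # subdivide wide intervals; linear interpolation of Cwb is exact there
  wide <- which(diff(t) > refine + 1e-12)
  if (length(wide)) {
    extra <- unlist(lapply(wide, function(j) {
      n_sub <- ceiling((t[j + 1] - t[j]) / refine)
      t[j] + (t[j + 1] - t[j]) * seq_len(n_sub - 1) / n_sub
    }))
    tt <- sort(c(t, extra))
    cwb <- approx(t, cwb, xout = tt)$y
    if (cp_explicit) cp <- approx(t, cp, xout = tt)$y
    t <- tt
  }
  if (!cp_explicit) cp <- cwb * p2wb_ratio * parent_fraction(pf_model, t)
  dt <- diff(t)
  cp_cum <- c(0, cumsum((cp[-length(cp)] + cp[-1]) / 2 * dt))
  structure(
    list(t_knots = t, cwb_knots = cwb, cp_knots = cp, cp_cum = cp_cum,
         p2wb_ratio = p2wb_ratio, pf_model = pf_model, label = label,
         cp_explicit = cp_explicit),
    class = "input_function"
  )
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function> %d knots to %.0f min, Cwb peak %.3g kBq/mL, R = %.3g%s\n",
    length(x$t_knots), max(x$t_knots), max(x$cwb_knots), x$p2wb_ratio,
    if (is.null(x$pf_model)) ", no metabolism" else ""))
  invisible(x)
}

#' Evaluate the whole-blood curve
#' @param inp An `input_function`.
#' @param t Times in minutes.
#' @return Cwb(t) in kBq/mL (constant extrapolation beyond the grid).
#' @export
if_cwb <- function(inp, t) {
  approx(inp$t_knots, inp$cwb_knots, xout = t, rule = 2)$y
}

#' Evaluate the metabolite-corrected parent-plasma curve
#' @inheritParams if_cwb
#' @return Cp(t) = Cwb(t) * R * pf(t) in kBq/mL, with the parent fraction
#'   evaluated exactly at `t` (not interpolated).
#' @export
if_cp <- function(inp, t) {
  if (isTRUE(inp$cp_explicit))
    return(approx(inp$t_knots, inp$cp_knots, xout = t, rule = 2)$y)
  if_cwb(inp, t) * inp$p2wb_ratio * parent_fraction(inp$pf_model, t)
}

#' Running integral of the parent-plasma curve
#' @inheritParams if_cwb
#' @return `integral from 0 to t of Cp(s) ds`, exact for the piecewise-linear
#'   representation (kBq*min/mL).
#' @export
if_cp_int <- function(inp, t) {
  tk <- inp$t_knots
  idx <- findInterval(pmin(t, tk[length(tk)]), tk, rightmost.closed = TRUE)
  tloc <- pmin(t, tk[length(tk)])
  cp_l <- inp$cp_knots[idx]
  cp_t <- approx(tk, inp$cp_knots, xout = tloc, rule = 2)$y
  out <- inp$cp_cum[idx] + (cp_l + cp_t) / 2 * (tloc - tk[idx])
  # constant extrapolation of Cp beyond the last knot
  over <- t > tk[length(tk)]
  if (any(over))
    out[over] <- out[over] +
      (t[over] - tk[length(tk)]) * inp$cp_knots[length(tk)]
  out
}

#' Closed-form whole-blood bolus input function
#'
#' Builds a synthetic whole-blood curve of the standard bolus form: a
#' gamma-variate-like rise multiplied by a tri-exponential decay,
#'
#'   Cwb(t) = A * (1 - exp(-(t/rise)^2)) * sum_i f_i exp(-mu_i t),
#'
#' normalized so the peak equals `peak_kbq_ml`. Defaults give an early peak
#' around 0.7 min and a slow late tail, the shape expected of a venous
#' whole-blood curve after a 1-2 min infusion of ~200 MBq of tracer.
#'
#' @param peak_kbq_ml Peak whole-blood activity, kBq/mL.
#' @param rise Rise-time constant, min.
#' @param frac Decay fractions (length 3, positive; normalized to sum 1).
#' @param rates Decay rates, 1/min (length 3, decreasing).
#' @param p2wb_ratio Plasma-to-whole-blood ratio; default 1.50.
#' @param pf_model Parent-fraction model; default [default_pf_model()].
#'   Pass `NULL` for a non-metabolized tracer.
#' @param t_max End of the knot grid, min.
#' @return An [input_function()].
#' @export
make_input_function <- function(peak_kbq_ml = 50, rise = 0.5,
                                frac = c(0.75, 0.20, 0.05),
                                rates = c(2.0, 0.12, 0.004),
                                p2wb_ratio = 1.50,
                                pf_model = default_pf_model(),
                                t_max = 130) {
  if (length(frac) != length(rates)) stop("frac and rates must match")
  if (any(frac < 0) || any(rates < 0) || rise <= 0 || peak_kbq_ml <= 0)
    stop("invalid-parameters: coefficients must be non-negative, rise > 0")
  frac <- frac / sum(frac)
  shape <- function(t) {
    (1 - exp(-(t / rise)^2)) *
      colSums(frac * exp(-outer(rates, t)))
  }
  tk <- sort(unique(c(seq(0, 3, by = 0.05), seq(3, 10, by = 0.25),
                      seq(10, t_max, by = 0.5))))
  v <- shape(tk)
  if (any(v < 0)) stop("invalid-parameters: curve is negative")
  pk <- which.max(v)
  if (tk[pk] > 2 || pk == length(v))
    stop("invalid-parameters: curve must have a single early peak (< 2 min)")
  input_function(tk, v / v[pk] * peak_kbq_ml, p2wb_ratio, pf_model,
                 label = "synthetic whole blood")
}
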