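# Independent numeric oracle for the two-tissue forward model: integrates
# the ODE system with a stiff solver (deSolve::lsoda) against the same
# piecewise-linear input representation, accumulating the integral of the
# measured signal so frame averages are exact up to solver tolerance.
ode_oracle_tac <- function(kp, inp, schedule, rtol = 1e-10, atol = 1e-12) {
  cpf <- approxfun(inp$t_knots, inp$cp_knots, rule = 2)
  cwbf <- approxfun(inp$t_knots, inp$cwb_knots, rule = 2)
  rhs <- function(t, y, p) {
    dc1 <- p$K1 * cpf(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2]
    dc2 <- p$k3 * y[1] - p$k4 * y[2]
    dsig <- (1 - p$vB) * (y[1] + y[2]) + p$vB * cwbf(t)
    list(c(dc1, dc2, dsig))
  }
  t_end <- max(schedule$end)
  tt <- sort(unique(c(0, schedule$start, schedule$end,
                      inp$t_knots[inp$t_knots <= t_end])))
  sol <- deSolve::ode(c(0, 0, 0), tt, rhs, as.list(unclass(kp)),
                      method = "lsoda", rtol = rtol, atol = atol)
  cum <- sol[, 4]
  i1 <- match(schedule$start, tt)
  i2 <- match(schedule$end, tt)
  tac(schedule$mid, schedule$dur, (cum[i2] - cum[i1]) / schedule$dur,
      label = "ODE oracle")
}

# relative error with a floor on the denominator so near-zero frames do not
# blow up the ratio (floor = 1e-3 of the curve maximum)
rel_err <- function(got, want) {
  ref <- pmax(abs(want), 1e-3 * max(abs(want)))
  max(abs(got - want) / ref)
}

# small two-region phantom (soft ellipsoid + aorta + two lesions) for fast
# end-to-end tests; 24 x 24 x 16 grid of 4 mm voxels
tiny_phantom_spec <- function(noise_alpha = 0, psf_fwhm_mm = 0, seed = 1,
                              schedule = default_schedule(),
                              input = make_input_function()) {
  soft <- kinetic_params(0.05, 0.20, 0.012, 0, 0.05)
  phantom_spec(
    dim = c(24, 24, 16), voxel_mm = 4,
    organs = list(
      list(name = "soft_tissue",
           shape = shape_ellipsoid(c(48, 48, 32), c(44, 44, 30)),
           params = soft),
      list(name = "aorta",
           shape = shape_cylinder(c(48, 70, 32), 9, 24, "z"),
           params = kinetic_params(0, 0, 0, 0, 1))),
    lesions = list(
      list(name = "lesion_a", center = c(28, 40, 32), diameter_mm = 18,
           params = kinetic_params(0.35, 0.30, 0.06, 0, 0.05)),
      list(name = "lesion_b", center = c(66, 34, 32), diameter_mm = 14,
           params = kinetic_params(0.25, 0.25, 0.05, 0, 0.05))),
    injected_dose_mbq = 200, body_weight_kg = 70,
    psf_fwhm_mm = psf_fwhm_mm, noise_alpha = noise_alpha, seed = seed,
    schedule = schedule, input = input)
}

# build-once cache for phantoms shared across test files
phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, spec_fn) {
  if (is.null(phantom_cache[[key]])) phantom_cache[[key]] <- build_phantom(spec_fn)
  phantom_cache[[key]]
}
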