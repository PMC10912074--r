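test_that("closed-form forward model matches the stiff-ODE oracle", {
  inp <- make_input_function()
  sch <- default_schedule()
  set.seed(42)
  for (i in 1:6) {
    kp <- kinetic_params(K1 = runif(1, 0.05, 0.8), k2 = runif(1, 0.05, 0.8),
                         k3 = runif(1, 0.005, 0.3),
                         k4 = sample(c(0, runif(1, 0.01, 0.2)), 1),
                         vB = runif(1, 0, 0.3))
    got <- model_tac(kp, inp, sch)
    want <- ode_oracle_tac(kp, inp, sch)
    expect_lt(rel_err(got$activity, want$activity), 1e-3)
  }
})

test_that("special parameter regimes reduce to the expected limits", {
  inp <- make_input_function()
  sch <- default_schedule()
  # k3 = k4 = 0: one-tissue model
  kp1 <- kinetic_params(0.2, 0.3, 0, 0, 0.1)
  expect_lt(rel_err(model_tac(kp1, inp, sch)$activity,
                    ode_oracle_tac(kp1, inp, sch)$activity), 1e-3)
  # repeated eigenvalue (k3 = 0, k2 = k4): analytic limit, no failure
  kpd <- kinetic_params(0.3, 0.25, 0, 0.25, 0.05)
  expect_lt(rel_err(model_tac(kpd, inp, sch)$activity,
                    ode_oracle_tac(kpd, inp, sch)$activity), 1e-3)
  # K1 = 0: pure blood signal
  kp0 <- kinetic_params(0, 0.1, 0.05, 0, 0.3)
  blood <- model_tac(kinetic_params(0, 0, 0, 0, 1), inp, sch)
  expect_equal(model_tac(kp0, inp, sch)$activity, 0.3 * blood$activity)
  # irreversible trapping approaches a plateau once pf has a zero floor
  long <- frame_schedule(seq(0, 580, by = 20), seq(20, 600, by = 20))
  inp0 <- make_input_function(pf_model = parent_fraction_model(5, 2, 0),
                              t_max = 620)
  y <- model_tac(kinetic_params(0.2, 0.2, 0.1, 0, 0), inp0, long)$activity
  n <- length(y)
  expect_lt(abs(y[n] - y[n - 1]) / y[n], 0.01)
})

test_that("forward model is linear in the input amplitude", {
  sch <- default_schedule()
  kp <- kinetic_params(0.3, 0.3, 0.05, 0.01, 0.1)
  inp1 <- make_input_function(peak_kbq_ml = 40)
  inp2 <- make_input_function(peak_kbq_ml = 80)
  expect_equal(2 * model_tac(kp, inp1, sch)$activity,
               model_tac(kp, inp2, sch)$activity, tolerance = 1e-12)
})

test_that("aic follows n log(rss/n) + 2p", {
  expect_equal(aic(30, 30, 4), 8)
  expect_equal(aic(10, 30, 4) - aic(10, 30, 5), -2)
  expect_equal(aic(10, 30, 4) - aic(5, 30, 4), 30 * log(2))
  expect_error(aic(1, 4, 5), "n > p")
  expect_warning(v <- aic(0, 30, 4), "-Inf")
  expect_identical(v, -Inf)
})

test_that("macro Ki is K1 k3 / (k2 + k3) with a zero-denominator guard", {
  expect_equal(macro_ki(kinetic_params(0.1, 0.1, 0.1)), 0.05)
  expect_equal(macro_ki(kinetic_params(0.1, 0.2, 0)), 0)
  expect_equal(macro_ki(kinetic_params(0.5, 0, 0)), 0)
})

test_that("noiseless irreversible parameters are recovered by the fit", {
  inp <- make_input_function()
  sch <- default_schedule()
  kp <- kinetic_params(0.35, 0.30, 0.06, 0, 0.05)
  y <- model_tac(kp, inp, sch)
  fit <- fit_2tcm(y, inp, sch, mode = "irreversible")
  expect_true(fit$converged)
  for (p in c("K1", "k2", "k3", "vB"))
    expect_equal(fit$params[[p]], kp[[p]], tolerance = 0.01)
  expect_equal(fit$ki, macro_ki(kp), tolerance = 0.01)
  expect_equal(fit$n_free_params, 4)
})

test_that("an all-zero TAC fits to K1 near zero", {
  inp <- make_input_function()
  sch <- default_schedule()
  z <- tac(sch$mid, sch$dur, rep(0, n_frames(sch)))
  # perfect fit of zero data hits the RSS = 0 sentinel
  expect_warning(fit <- fit_2tcm(z, inp, sch, mode = "irreversible",
                                 n_starts = 1), "-Inf")
  expect_lt(fit$params$K1, 1e-6)
})

test_that("reversible fit never has higher RSS than irreversible (nesting)", {
  inp <- make_input_function()
  sch <- default_schedule()
  kp <- kinetic_params(0.35, 0.30, 0.06, 0.02, 0.05)
  for (seed in 1:3) {
    y <- simulate_tac(kp, inp, sch, seed = seed)
    f_irr <- fit_2tcm(y, inp, sch, mode = "irreversible", seed = seed)
    f_rev <- fit_2tcm(y, inp, sch, mode = "reversible", seed = seed)
    expect_lte(f_rev$rss, f_irr$rss * (1 + 1e-6))
  }
})

test_that("model comparison applies the delta-AIC sign convention", {
  mk <- function(mode, aic_val) structure(
    list(mode = mode, aic = aic_val, n_frames = 41, weights = rep(1, 41)),
    class = "fit_2tcm")
  cmp <- compare_models(mk("reversible", 10), mk("irreversible", 5))
  expect_equal(cmp$delta_aic, 5)
  expect_equal(cmp$preferred, "irreversible")
  expect_true(cmp$significant)
  cmp2 <- compare_models(mk("reversible", 5), mk("irreversible", 6.5))
  expect_equal(cmp2$preferred, "reversible")
  expect_false(cmp2$significant)
  expect_equal(select_model(cmp2), "irreversible")  # parsimony below threshold
  expect_equal(select_model(compare_models(mk("reversible", 5),
                                           mk("irreversible", 10))),
               "reversible")
  bad <- mk("irreversible", 5); bad$n_frames <- 40
  expect_error(compare_models(mk("reversible", 10), bad), "same number")
})

test_that("fit results are deterministic given the seed", {
  inp <- make_input_function()
  sch <- default_schedule()
  y <- simulate_tac(kinetic_params(0.3, 0.3, 0.05, 0, 0.05), inp, sch,
                    seed = 11)
  f1 <- fit_2tcm(y, inp, sch, mode = "reversible", seed = 3)
  f2 <- fit_2tcm(y, inp, sch, mode = "reversible", seed = 3)
  expect_identical(unclass(f1$params), unclass(f2$params))
})
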