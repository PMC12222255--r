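test_that("macro-parameter formulas reproduce hand arithmetic", {
  expect_equal(ki_macro(0.8, 1.2, 0.4), 0.2)
  expect_equal(ki_macro(0.5, 1, 0), 0)
  expect_equal(ki_macro(0.7, 0, 0.3), 0.7)  # full trapping
  expect_equal(vt_macro(0.3, 0.15), 2)
  expect_equal(vt_macro(0, 0.2), 0)
  expect_equal(vt_macro(0.3 * 5, 0.15 * 5), 2)  # rate-scaling invariance
  expect_error(ki_macro(0.5, 0, 0), class = "dynapet_error")
  expect_error(vt_macro(0.5, 0), class = "dynapet_error")

  set.seed(20)
  for (i in 1:20) {
    K1 <- runif(1, 0, 2); k2 <- runif(1, 0.01, 2); k3 <- runif(1, 0, 1)
    expect_identical(ki_macro(K1, k2, k3), K1 * k3 / (k2 + k3))
    expect_identical(vt_macro(K1, k2), K1 / k2)
  }
})

test_that("1-TCM limits: pure integrator and pure blood", {
  t_s <- grid_3600()
  cp <- default_cp()
  # k2 = 0, vB = 0: CT = K1 * int Cp
  p0 <- kinetic_params(0.5, 0)
  ct <- model_tac_1tcm(p0, cp$value, t_s)
  expect_equal(ct, 0.5 / 60 * dynapet:::cum_trapz(cp$value, t_s),
               tolerance = 1e-9)
  # vB = 1: measured curve is the blood curve
  pb <- kinetic_params(0.3, 0.2, vB = 1)
  expect_equal(model_tac_1tcm(pb, cp$value, t_s), cp$value, tolerance = 1e-12)
})

test_that("2-TCM nests the 1-TCM at k3 = 0", {
  t_s <- grid_3600()
  cp <- default_cp()
  p <- kinetic_params(0.4, 0.3, 0, vB = 0.07, delay_s = 8)
  expect_equal(model_tac_2tcm_irr(p, cp$value, t_s),
               model_tac_1tcm(p, cp$value, t_s), tolerance = 1e-12)
})

test_that("forward models agree with an independent ODE oracle within 0.1%", {
  t_s <- grid_3600()
  cp <- default_cp()
  set.seed(31)
  for (i in 1:10) {
    p2 <- kinetic_params(runif(1, 0.1, 1.5), runif(1, 0.1, 1.5),
                         runif(1, 0.01, 0.8), vB = runif(1, 0, 0.3),
                         delay_s = sample(0:20, 1))
    got <- model_tac_2tcm_irr(p2, cp$value, t_s)
    ref <- ode_oracle_tac(p2, cp$value, t_s, "2tcm_irr")
    expect_lt(max(abs(got - ref)) / max(ref), 1e-3)

    p1 <- kinetic_params(runif(1, 0.1, 1), runif(1, 0.05, 1),
                         vB = runif(1, 0, 0.3), delay_s = sample(0:20, 1))
    got1 <- model_tac_1tcm(p1, cp$value, t_s)
    ref1 <- ode_oracle_tac(p1, cp$value, t_s, "1tcm")
    expect_lt(max(abs(got1 - ref1)) / max(ref1), 1e-3)
  }
})

test_that("late Patlak slope of the 2-TCM forward curve approaches Ki", {
  t_s <- grid_3600()
  cp <- default_cp()
  p <- kinetic_params(0.6, 0.8, 0.25)
  ct <- model_tac_2tcm_irr(p, cp$value, t_s)
  icp <- dynapet:::cum_trapz(cp$value, t_s)
  use <- t_s >= 1800
  slope <- stats::coef(stats::lsfit(icp[use] / cp$value[use] / 60,
                                    ct[use] / cp$value[use]))[2]
  expect_equal(unname(slope), ki_macro(0.6, 0.8, 0.25), tolerance = 0.01)
})

test_that("dual blood input mixes artery with a unit-mass dispersed portal curve", {
  t_s <- grid_3600()
  ca <- default_cp()$value
  expect_equal(dual_input(ca, t_s, fa = 1, ka = 1), ca)
  # dispersion kernel has unit mass: long-horizon integrals agree within 1%
  cpv <- dual_input(ca, t_s, fa = 0, ka = 1)
  expect_lt(abs(sum(cpv) - sum(ca)) / sum(ca), 0.01)
  # infinitely fast dispersion recovers the arterial curve after the peak
  fast <- dual_input(ca, t_s, fa = 0, ka = 100)
  post <- t_s > 120
  expect_lt(max(abs(fast[post] - ca[post]) / ca[post]), 0.02)
  expect_error(dual_input(ca, t_s, fa = 2), class = "dynapet_error")
  expect_error(dual_input(ca, t_s, ka = 0), class = "dynapet_error")
})

test_that("noiseless simulate-and-refit recovers micro and macro parameters", {
  t_s <- grid_3600()
  cp <- default_cp()
  p <- kinetic_params(0.8, 1.2, 0.4, vB = 0.05, delay_s = 10)
  tac <- tac_from_curve(model_tac_2tcm_irr(p, cp$value, t_s), t_s, sched_39())
  fit <- fit_compartment(tac, cp, "2tcm_irr", opts = light_opts())
  expect_true(fit$converged)
  expect_lt(abs(fit$macro[["Ki"]] - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$params$delay_s - 10), 1)

  p1 <- kinetic_params(0.3, 0.15, vB = 0.03, delay_s = 6)
  t30 <- seq(0, 1800, 1)
  cp30 <- feng_if(if_params(), t30)
  tac1 <- tac_from_curve(model_tac_1tcm(p1, cp30$value, t30), t30, sched_44())
  fit1 <- fit_compartment(tac1, cp30, "1tcm", opts = light_opts())
  expect_lt(abs(fit1$macro[["VT"]] - 2) / 2, 0.01)

  expect_error(fit_compartment(
    dynapet:::new_tac(sched_39()$mid_s, rep(0, 39), 0, "kBq/ml"), cp),
    class = "dynapet_error")
})

test_that("injected delays on a 1-s grid are recovered within one step", {
  t_s <- grid_3600()
  cp <- default_cp()
  opts <- fit_options(delay_grid_s = seq(0, 20, 1), multistart = 2)
  for (d0 in c(3, 11)) {
    p <- kinetic_params(0.5, 0.6, 0.15, vB = 0.04, delay_s = d0)
    tac <- tac_from_curve(model_tac_2tcm_irr(p, cp$value, t_s), t_s, sched_39())
    fit <- fit_compartment(tac, cp, "2tcm_irr", opts = opts)
    expect_lt(abs(fit$params$delay_s - d0), 1 + 1e-6)
  }
})

test_that("fit results expose tidy() and glance()", {
  t_s <- grid_3600()
  cp <- default_cp()
  p <- kinetic_params(0.4, 0.5, 0.1, vB = 0.02)
  tac <- tac_from_curve(model_tac_2tcm_irr(p, cp$value, t_s), t_s, sched_39())
  fit <- fit_compartment(tac, cp, "2tcm_irr",
                         opts = fit_options(delay_grid_s = 0, multistart = 2))
  td <- generics::tidy(fit)
  expect_true(all(c("K1", "k2", "k3", "Ki") %in% td$term))
  gl <- generics::glance(fit)
  expect_equal(gl$model, "2tcm_irr")
  expect_true(gl$converged)
  expect_equal(gl$macro_value,
               ki_macro(td$estimate[td$term == "K1"],
                        td$estimate[td$term == "k2"],
                        td$estimate[td$term == "k3"]))
})
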