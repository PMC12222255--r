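# Shared fixtures, built lazily once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# the 60-min FDG protocol: 12x5s, 6x10s, 3x20s, 2x30s, 6x1min, 10x5min
sched_39 <- function() fx_get("sched39", function() {
  parse_schedule_spec(tibble::tibble(count = c(12, 6, 3, 2, 6, 10),
                                     duration_s = c(5, 10, 20, 30, 60, 300)))
})

# the 30-min protocol: 24x5s, 6x10s, 3x20s, 2x30s, 5x1min, 4x5min
sched_44 <- function() fx_get("sched44", function() {
  parse_schedule_spec(tibble::tibble(count = c(24, 6, 3, 2, 5, 4),
                                     duration_s = c(5, 10, 20, 30, 60, 300)))
})

grid_3600 <- function() seq(0, 3600, by = 1)

default_cp <- function() fx_get("cp3600", function() {
  feng_if(if_params(), grid_3600())
})

demo_bundle <- function() fx_get("bundle", function() default_phantom("small"))

# noiseless 39-frame rendering of the demo phantom
clean_dynamic <- function() fx_get("clean39", function() {
  render_dynamic(demo_bundle()$phantom, demo_bundle()$if_params, sched_39())
})

# a TAC object from a gridded model curve
tac_from_curve <- function(curve, t_s, schedule) {
  v <- dynapet:::frame_average(curve, t_s, schedule)
  tac <- tibble::tibble(mid_s = schedule$mid_s, mean = v,
                        sd = 0, units = "kBq/ml")
  class(tac) <- c("pet_tac", class(tac))
  attr(tac, "schedule") <- schedule
  tac
}

# light fitting options used in bulk tests (coarser delay grid)
light_opts <- function() fit_options(delay_grid_s = seq(0, 20, by = 2),
                                     multistart = 3)

# independent ODE oracle for the compartment forward models (deSolve),
# fed by linear interpolation of the gridded input function
ode_oracle_tac <- function(params, cpv, t_s, model = c("2tcm_irr", "1tcm")) {
  model <- match.arg(model)
  cp_fun <- stats::approxfun(t_s, cpv, rule = 2)
  delay <- params$delay_s
  k1 <- params$K1 / 60; k2 <- params$k2 / 60; k3 <- params$k3 / 60
  deriv <- function(t, y, parms) {
    cpd <- if (t - delay < 0) 0 else cp_fun(t - delay)
    if (model == "1tcm") {
      list(c(k1 * cpd - k2 * y[1]))
    } else {
      list(c(k1 * cpd - (k2 + k3) * y[1], k3 * y[1]))
    }
  }
  y0 <- if (model == "1tcm") c(0) else c(0, 0)
  sol <- deSolve::lsoda(y0, t_s, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  ct <- if (model == "1tcm") sol[, 2] else sol[, 2] + sol[, 3]
  cpd <- ifelse(t_s - delay < 0, 0, cp_fun(t_s - delay))
  (1 - params$vB) * ct + params$vB * cpd
}
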