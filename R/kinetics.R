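#' Kinetic micro-parameters for compartment models
#'
#' Rates follow the usual PET convention: `K1` in ml.min^-1.cm^-3 is uptake
#' from blood into tissue, `k2` (min^-1) clearance back to blood, `k3`
#' (min^-1) the trapping (phosphorylation) rate, `k4` (min^-1) release from
#' the trapped pool (fixed 0 for the irreversible model), `vB` the fractional
#' blood volume contributing blood signal to the measured curve, and
#' `delay_s` the arrival delay of the input function at the tissue (s).
#'
#' @param K1,k2,k3,k4 Non-negative rate constants (see description).
#' @param vB Blood-volume fraction in \[0, 1\].
#' @param delay_s Blood delay in seconds (may be negative).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0, delay_s = 0) {
  if (any(c(K1, k2, k3, k4) < 0) || any(!is.finite(c(K1, k2, k3, k4)))) {
    abort_dynapet("Rate constants must be finite and >= 0.")
  }
  if (vB < 0 || vB > 1) abort_dynapet("`vB` must lie in [0, 1].")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB,
                 delay_s = delay_s),
            class = "kinetic_params")
}

#' Net influx rate Ki for the irreversible 2-tissue model
#'
#' `Ki = K1 * k3 / (k2 + k3)` in ml.min^-1.cm^-3: the steady-state rate at
#' which tracer is metabolically trapped.
#'
#' @param K1,k2,k3 Rate constants (see [kinetic_params()]); `k2 + k3` must be
#'   positive.
#' @return Ki (ml.min^-1.cm^-3).
#' @examples
#' ki_macro(0.8, 1.2, 0.4) # 0.2
#' @export
ki_macro <- function(K1, k2, k3) {
  if (any(k2 + k3 <= 0)) abort_dynapet("`k2 + k3` must be > 0 for Ki.")
  K1 * k3 / (k2 + k3)
}

#' Total volume of distribution VT for the 1-tissue model
#'
#' `VT = K1 / k2` in ml.cm^-3, the equilibrium tissue-to-plasma
#' concentration ratio.
#'
#' @param K1,k2 Rate constants; `k2` must be positive.
#' @return VT (ml.cm^-3).
#' @examples
#' vt_macro(0.3, 0.15) # 2
#' @export
vt_macro <- function(K1, k2) {
  if (any(k2 <= 0)) abort_dynapet("`k2` must be > 0 for VT.")
  K1 / k2
}

# ---- convolution primitives ----------------------------------------------
# All continuous-time curves live on a uniform grid t_s (seconds).  The
# input is treated as piecewise linear between grid points, for which the
# convolution with an exponential kernel has a closed-form per-step update,
# evaluated as a linear recurrence.  This avoids quadrature drift at early
# 5-s frames without needing a finer grid.

# y(t) = int_0^t exp(-k (t - s)) f(s) ds, k in s^-1, f piecewise linear.
exp_conv <- function(f, t_s, k_per_s) {
  n <- length(t_s)
  if (n < 2L) return(numeric(n))
  h <- t_s[2] - t_s[1]
  if (k_per_s * h < 1e-12) return(cum_trapz(f, t_s))
  E <- exp(-k_per_s * h)
  c0 <- f[-n]
  dl <- f[-1] - f[-n]
  b <- c0 * (1 - E) / k_per_s + dl / h * (h / k_per_s - (1 - E) / k_per_s^2)
  c(0, as.numeric(stats::filter(b, E, method = "recursive")))
}

cum_trapz <- function(f, t_s) {
  n <- length(t_s)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((f[-1] + f[-n]) / 2 * diff(t_s)))
}

shift_curve <- function(f, t_s, delay_s) {
  if (abs(delay_s) < 1e-12) return(f)
  stats::approx(t_s, f, xout = t_s - delay_s, yleft = 0,
                yright = f[length(f)])$y
}

check_grid <- function(t_s) {
  if (length(t_s) < 2L || any(diff(t_s) <= 0)) {
    abort_dynapet("Time grid must be ascending with >= 2 points.")
  }
  h <- diff(t_s)
  if (max(h) - min(h) > 1e-9) {
    abort_dynapet("Time grid must be uniform.")
  }
}

#' Forward 1-tissue-compartment model
#'
#' Tissue response `CT(t) = K1 exp(-k2 t) (*) Cp(t - delay)` plus the blood
#' contribution: the measured curve is `(1 - vB) CT + vB Cb` with the whole
#' blood curve identified with plasma (`Cb = Cp`).
#'
#' @param params A [kinetic_params()] (`k3`, `k4` ignored).
#' @param cp Input-function concentration sampled on `t_s` (kBq/ml).
#' @param t_s Uniform ascending time grid in seconds.
#' @return Measured concentration on `t_s` (kBq/ml).
#' @export
model_tac_1tcm <- function(params, cp, t_s) {
  stopifnot(inherits(params, "kinetic_params"))
  check_grid(t_s)
  cpd <- shift_curve(cp, t_s, params$delay_s)
  ct <- (params$K1 / 60) * exp_conv(cpd, t_s, params$k2 / 60)
  (1 - params$vB) * ct + params$vB * cpd
}

#' Forward irreversible 2-tissue-compartment model (k4 = 0)
#'
#' With `a = k2 + k3`, the tissue curve decomposes into a trapped term
#' `Ki * int Cp` (with `Ki = K1 k3 / a`) and a reversible term
#' `(K1 k2 / a) exp(-a t) (*) Cp`. The measured curve adds fractional blood
#' volume as in [model_tac_1tcm()]. The degenerate case `k2 = k3 = 0` is the
#' pure integrator `K1 int Cp`.
#'
#' @inheritParams model_tac_1tcm
#' @return Measured concentration on `t_s` (kBq/ml).
#' @export
model_tac_2tcm_irr <- function(params, cp, t_s) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k4 != 0) abort_dynapet("Irreversible model requires k4 = 0.")
  check_grid(t_s)
  cpd <- shift_curve(cp, t_s, params$delay_s)
  a <- (params$k2 + params$k3) / 60
  if (a <= 0) {
    ct <- (params$K1 / 60) * cum_trapz(cpd, t_s)
  } else {
    ki_s <- (params$K1 / 60) * (params$k3 / 60) / a
    ct <- ki_s * cum_trapz(cpd, t_s) +
      (params$K1 / 60) * (params$k2 / 60) / a * exp_conv(cpd, t_s, a)
  }
  (1 - params$vB) * ct + params$vB * cpd
}

#' Simplified dual-blood input for the liver
#'
#' The liver receives blood from the hepatic artery (arterial curve `Ca`)
#' and the portal vein, modelled as the arterial curve dispersed through a
#' unit-mass exponential kernel `ka exp(-ka t)`:
#' `C_dual = fa Ca + (1 - fa) (Ca (*) ka exp(-ka t))`.
#'
#' @param ca Arterial input on `t_s` (kBq/ml).
#' @param t_s Uniform time grid, seconds.
#' @param fa Arterial flow fraction in \[0, 1\] (default 0.25).
#' @param ka Portal dispersion rate, min^-1 (> 0; default 1).
#' @return Dual blood curve on `t_s`.
#' @export
dual_input <- function(ca, t_s, fa = 0.25, ka = 1) {
  if (fa < 0 || fa > 1) abort_dynapet("`fa` must lie in [0, 1].")
  if (!is.finite(ka) || ka <= 0) abort_dynapet("`ka` must be > 0.")
  check_grid(t_s)
  cpv <- (ka / 60) * exp_conv(ca, t_s, ka / 60)
  fa * ca + (1 - fa) * cpv
}

# duration-weighted average of a gridded curve over each frame interval
frame_average <- function(curve, t_s, schedule) {
  cumint <- cum_trapz(curve, t_s)
  Cs <- stats::approx(t_s, cumint, xout = schedule$start_s, rule = 2)$y
  Ce <- stats::approx(t_s, cumint, xout = schedule$end_s, rule = 2)$y
  (Ce - Cs) / schedule$dur_s
}

# rebuild a contiguous schedule starting at 0 from frame mid-times
infer_schedule_from_mids <- function(mid_s) {
  b <- numeric(length(mid_s) + 1)
  for (i in seq_along(mid_s)) b[i + 1] <- 2 * mid_s[i] - b[i]
  if (any(diff(b) <= 0)) {
    abort_dynapet("Cannot infer a contiguous schedule from these mid-times; supply `schedule`.")
  }
  frame_schedule(b[-length(b)], b[-1])
}

#' Fitting options for compartment models
#'
#' @param bounds Named list of `c(lower, upper)` for `K1`, `k2`, `k3`, `vB`.
#' @param weights `"uniform"` (default) or `"duration"` (weight residuals by
#'   sqrt of frame duration).
#' @param delay_grid_s Candidate delays searched by grid + parabolic
#'   refinement, seconds.
#' @param multistart Number of random restarts for the rate parameters.
#' @param tol Relative convergence tolerance handed to the optimizer.
#' @param seed Seed for the multistart draws (local RNG; the global RNG
#'   state is untouched).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(bounds = list(K1 = c(0, 5), k2 = c(0, 5),
                                      k3 = c(0, 5), vB = c(0, 0.5)),
                        weights = c("uniform", "duration"),
                        delay_grid_s = seq(-30, 30, by = 1),
                        multistart = 5, tol = 1e-9, seed = 42) {
  weights <- match.arg(weights)
  for (b in bounds) {
    if (any(!is.finite(b)) || b[1] > b[2]) {
      abort_dynapet("Bounds must be finite with lower <= upper.")
    }
  }
  structure(list(bounds = bounds, weights = weights,
                 delay_grid_s = delay_grid_s, multistart = multistart,
                 tol = tol, seed = seed),
            class = "fit_options")
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fit a compartment model to a region TAC
#'
#' Weighted nonlinear least squares over the rate parameters (`K1`, `k2`,
#' `k3` for the irreversible 2-tissue model, `K1`, `k2` for the 1-tissue
#' model) and the blood-volume fraction `vB`, via bounded
#' Levenberg-Marquardt with multistart. The blood delay is resolved by a
#' grid search over `delay_grid_s` followed by parabolic refinement of the
#' objective around the best grid point.
#'
#' @param tac A `pet_tac` (>= 6 frames). If it carries a `schedule`
#'   attribute (as TACs from [roi_extract()] do), model predictions are
#'   frame-duration averages; otherwise a contiguous schedule is inferred
#'   from the mid-times.
#' @param cp Blood input: a data frame with columns `t_s` (uniform grid,
#'   seconds, at least as dense as the TAC) and `value` (kBq/ml).
#' @param model `"2tcm_irr"` or `"1tcm"`.
#' @param opts A [fit_options()].
#' @param schedule Optional [frame_schedule()] overriding the attribute.
#' @return A list of class `compartment_fit`: `params`
#'   ([kinetic_params()]), `macro` (named `Ki` or `VT`), `objective`
#'   (weighted SSE), `converged`, `n_frames_used`, `model`, and a `fitted`
#'   tibble (mid_s, observed, fitted).
#' @export
fit_compartment <- function(tac, cp, model = c("2tcm_irr", "1tcm"),
                            opts = fit_options(), schedule = NULL) {
  model <- match.arg(model)
  if (nrow(tac) < 6L) abort_dynapet("Need at least 6 frames to fit.")
  if (all(abs(tac$mean) < 1e-300)) abort_dynapet("TAC is all zero; nothing to fit.")
  schedule <- schedule %||% attr(tac, "schedule") %||%
    infer_schedule_from_mids(tac$mid_s)
  t_s <- cp$t_s
  cpv <- cp$value
  check_grid(t_s)
  if (max(schedule$end_s) > max(t_s) + 1e-6) {
    abort_dynapet("Input function grid must cover the TAC's time span.")
  }
  w <- switch(opts$weights,
              uniform = rep(1, nrow(schedule)),
              duration = sqrt(schedule$dur_s / mean(schedule$dur_s)))
  obs <- tac$mean

  free <- if (model == "2tcm_irr") c("K1", "k2", "k3", "vB") else c("K1", "k2", "vB")
  lo <- vapply(opts$bounds[free], `[`, 0, 1)
  hi <- vapply(opts$bounds[free], `[`, 0, 2)

  predict_frames <- function(theta, delay) {
    p <- kinetic_params(K1 = theta[["K1"]], k2 = theta[["k2"]],
                        k3 = if (model == "2tcm_irr") theta[["k3"]] else 0,
                        vB = theta[["vB"]], delay_s = delay)
    curve <- if (model == "2tcm_irr") model_tac_2tcm_irr(p, cpv, t_s)
             else model_tac_1tcm(p, cpv, t_s)
    frame_average(curve, t_s, schedule)
  }
  resid_fn <- function(theta, delay) {
    names(theta) <- free
    w * (obs - predict_frames(theta, delay))
  }
  run_lm <- function(start, delay, maxit = 100) {
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lo, upper = hi, fn = resid_fn, delay = delay,
      control = minpack.lm::nls.lm.control(
        maxiter = maxit, ftol = opts$tol, ptol = opts$tol)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  starts <- with_local_seed(opts$seed, {
    base <- pmin(pmax(c(K1 = 0.1, k2 = 0.1, k3 = 0.01, vB = 0.05)[free], lo), hi)
    extra <- if (opts$multistart > 1) {
      lapply(seq_len(opts$multistart - 1), function(i) {
        s <- lo + stats::runif(length(free)) * (pmin(hi, c(K1 = 2, k2 = 2, k3 = 1, vB = 0.5)[free]) - lo)
        setNames(s, free)
      })
    } else list()
    c(list(base), extra)
  })

  # multistart at the central delay, then track the best fit across the grid
  delay0 <- opts$delay_grid_s[which.min(abs(opts$delay_grid_s))]
  fits0 <- lapply(starts, run_lm, delay = delay0)
  fits0 <- Filter(Negate(is.null), fits0)
  if (!length(fits0)) abort_dynapet("Optimizer failed at every start.")
  best0 <- fits0[[which.min(vapply(fits0, function(f) f$deviance, 0))]]

  sse_at <- function(delay, start) {
    f <- run_lm(start, delay)
    if (is.null(f)) return(list(sse = Inf, fit = NULL))
    list(sse = f$deviance, fit = f)
  }
  grid <- opts$delay_grid_s
  sses <- numeric(length(grid))
  cur <- stats::coef(best0)
  fits <- vector("list", length(grid))
  ord <- order(abs(grid - delay0))  # walk outward from the centre, warm-started
  for (i in ord) {
    r <- sse_at(grid[i], cur)
    sses[i] <- r$sse
    fits[[i]] <- r$fit
    if (!is.null(r$fit)) cur <- stats::coef(r$fit)
  }
  ibest <- which.min(sses)
  d_best <- grid[ibest]
  # parabolic refinement on the objective through the best point and its
  # neighbours (only when strictly interior)
  if (ibest > 1 && ibest < length(grid) &&
      is.finite(sses[ibest - 1]) && is.finite(sses[ibest + 1])) {
    y1 <- sses[ibest - 1]; y2 <- sses[ibest]; y3 <- sses[ibest + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) {
      step <- grid[ibest + 1] - grid[ibest]
      d_ref <- d_best + 0.5 * step * (y1 - y3) / denom
      r <- sse_at(d_ref, stats::coef(fits[[ibest]]))
      if (r$sse < sses[ibest]) {
        d_best <- d_ref
        fits[[ibest]] <- r$fit
      }
    }
  }
  final <- fits[[ibest]]
  if (is.null(final)) abort_dynapet("Optimizer failed at the selected delay.")
  th <- stats::coef(final)
  names(th) <- free
  pars <- kinetic_params(K1 = th[["K1"]], k2 = th[["k2"]],
                         k3 = if (model == "2tcm_irr") th[["k3"]] else 0,
                         vB = th[["vB"]], delay_s = d_best)
  macro <- if (model == "2tcm_irr") {
    c(Ki = if (th[["k2"]] + th[["k3"]] > 0) ki_macro(th[["K1"]], th[["k2"]], th[["k3"]]) else 0)
  } else {
    c(VT = if (th[["k2"]] > 0) vt_macro(th[["K1"]], th[["k2"]]) else NA_real_)
  }
  converged <- final$info %in% 1:3
  structure(list(
    params = pars, macro = macro, model = model,
    objective = final$deviance, converged = converged,
    n_frames_used = nrow(schedule),
    fitted = tibble(mid_s = tac$mid_s, observed = obs,
                    fitted = predict_frames(th, d_best))
  ), class = "compartment_fit")
}

#' @export
print.compartment_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<compartment_fit> %s: K1=%.4f k2=%.4f k3=%.4f vB=%.3f delay=%.1fs\n",
              x$model, p$K1, p$k2, p$k3, p$vB, p$delay_s))
  cat(sprintf("  %s = %.5f | SSE = %.4g | converged: %s\n",
              names(x$macro), x$macro, x$objective, x$converged))
  invisible(x)
}
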