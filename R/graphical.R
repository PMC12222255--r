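# cumulative trapezoid over frame mid-times with a zero anchor at t = 0
tac_cum_int <- function(mid_s, vals) {
  x <- c(0, mid_s)
  y <- cbind(0, vals)  # vals: matrix (series x frames) or vector
  if (is.null(dim(vals))) y <- rbind(c(0, vals))
  dx <- diff(x)
  incr <- (y[, -1, drop = FALSE] + y[, -ncol(y), drop = FALSE]) / 2 *
    rep(dx, each = nrow(y))
  t(apply(incr, 1, cumsum))
}

interp_on <- function(curve, xout) {
  stats::approx(curve$t_s, curve$value, xout = xout, rule = 2)$y
}

graphical_ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  list(slope = slope, intercept = intercept, n_points = n, r_squared = r2)
}

new_graphical_result <- function(fit, kind, tstar_min) {
  structure(c(fit, list(kind = kind, tstar_min = tstar_min,
                        macro = setNames(fit$slope,
                                         if (kind == "patlak") "Ki" else "VT"))),
            class = "graphical_result")
}

#' @export
print.graphical_result <- function(x, ...) {
  cat(sprintf("<graphical_result> %s (t* = %g min): %s = %.5f, intercept %.4f, n = %d, R^2 = %.4f\n",
              x$kind, x$tstar_min, names(x$macro), x$slope, x$intercept,
              x$n_points, x$r_squared))
  invisible(x)
}

#' Patlak graphical analysis of a region TAC
#'
#' For an irreversibly trapped tracer, `CT(t)/Cp(t)` plotted against
#' `int_0^t Cp / Cp(t)` becomes linear after an equilibrium time t*; the
#' slope is the net influx rate Ki. Ordinary least squares over frames with
#' mid-time >= t*.
#'
#' @param tac A `pet_tac`.
#' @param cp Blood curve: data frame with `t_s` (1-s grid recommended) and
#'   `value`; integrated by trapezoid from t = 0.
#' @param tstar_min Equilibrium time t* in minutes (default 25).
#' @return A `graphical_result` with `slope` (Ki, ml.min^-1.cm^-3),
#'   `intercept`, `n_points`, `r_squared`.
#' @export
patlak_roi <- function(tac, cp, tstar_min = 25) {
  use <- which(tac$mid_s >= tstar_min * 60 - 1e-9)
  if (length(use) < 2L) abort_dynapet("Need >= 2 frames with mid-time beyond t*.")
  mid <- tac$mid_s[use]
  cpm <- interp_on(cp, mid)
  if (any(cpm <= 0)) abort_dynapet("Cp must be positive at all used frames.")
  icp <- stats::approx(cp$t_s, cum_trapz(cp$value, cp$t_s), mid, rule = 2)$y
  # x in minutes so the slope carries ml.min^-1.cm^-3
  fit <- graphical_ols(icp / cpm / 60, tac$mean[use] / cpm)
  new_graphical_result(fit, "patlak", tstar_min)
}

#' Logan graphical analysis of a region TAC
#'
#' For reversible tracers, `int_0^t CT / CT(t)` against `int_0^t Cp / CT(t)`
#' becomes linear after t*; the slope is the total volume of distribution
#' VT. The tissue integral uses the trapezoid rule over frame mid-times with
#' a zero anchor at t = 0.
#'
#' @inheritParams patlak_roi
#' @param tstar_min Equilibrium time t* in minutes (default 2).
#' @return A `graphical_result` with `slope` (VT, ml.cm^-3).
#' @export
logan_roi <- function(tac, cp, tstar_min = 2) {
  if (all(abs(tac$mean) < 1e-300)) abort_dynapet("TAC is all zero.")
  use <- which(tac$mid_s >= tstar_min * 60 - 1e-9)
  if (length(use) < 2L) abort_dynapet("Need >= 2 frames with mid-time beyond t*.")
  ict_all <- drop(tac_cum_int(tac$mid_s, tac$mean))
  ct <- tac$mean[use]
  if (any(ct <= 0)) abort_dynapet("CT must be positive at all used frames.")
  mid <- tac$mid_s[use]
  icp <- stats::approx(cp$t_s, cum_trapz(cp$value, cp$t_s), mid, rule = 2)$y
  fit <- graphical_ols(icp / ct, ict_all[use] / ct)
  new_graphical_result(fit, "logan", tstar_min)
}

new_parametric_map <- function(slope, intercept, mask, tstar_min, kind) {
  slope[!mask] <- 0
  intercept[!mask] <- 0
  structure(list(slope = slope, intercept = intercept, mask = mask,
                 tstar_min = tstar_min, kind = kind),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s (t* = %g min): %d fitted voxels, slope range [%.4g, %.4g]\n",
              x$kind, x$tstar_min, sum(x$mask),
              min(x$slope[x$mask]), max(x$slope[x$mask])))
  invisible(x)
}

#' Voxelwise Patlak / Logan parametric maps
#'
#' Applies [patlak_roi()] / [logan_roi()] to every in-mask voxel series
#' (vectorized). Voxels failing the preconditions (non-positive tissue
#' values at used frames, for Logan) are excluded from the output mask
#' rather than clamped; negative slopes are retained so noise-induced bias
#' stays measurable. Values outside the fitted mask are exactly 0.
#'
#' @param image A [dynamic_image()].
#' @param cp Blood curve as in [patlak_roi()].
#' @param tstar_min Equilibrium time in minutes.
#' @param mask 3D logical array of candidate voxels.
#' @return A `parametric_map`: 3D `slope` and `intercept` arrays, the
#'   fitted-voxel `mask`, `tstar_min` and `kind`.
#' @export
patlak_image <- function(image, cp, tstar_min = 25, mask = NULL) {
  vox_graphical(image, cp, tstar_min, mask, kind = "patlak")
}

#' @rdname patlak_image
#' @export
logan_image <- function(image, cp, tstar_min = 2, mask = NULL) {
  vox_graphical(image, cp, tstar_min, mask, kind = "logan")
}

vox_graphical <- function(image, cp, tstar_min, mask, kind) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), d[1:3])
  if (!sum(mask)) abort_dynapet("Mask is empty.")
  mid <- image$schedule$mid_s
  use <- which(mid >= tstar_min * 60 - 1e-9)
  if (length(use) < 2L) abort_dynapet("Need >= 2 frames with mid-time beyond t*.")
  idxv <- which(mask)
  V <- matrix(image$voxels, prod(d[1:3]), d[4])[idxv, , drop = FALSE]
  icp <- stats::approx(cp$t_s, cum_trapz(cp$value, cp$t_s), mid[use], rule = 2)$y
  if (kind == "patlak") {
    cpm <- interp_on(cp, mid[use])
    if (any(cpm <= 0)) abort_dynapet("Cp must be positive at all used frames.")
    X <- matrix(icp / cpm / 60, nrow = length(idxv), ncol = length(use),
                byrow = TRUE)
    Y <- V[, use, drop = FALSE] / rep(cpm, each = length(idxv))
    ok <- rep(TRUE, length(idxv))
  } else {
    ict <- tac_cum_int(mid, V)
    ct <- V[, use, drop = FALSE]
    ok <- rowSums(ct <= 0) == 0
    X <- rep(icp, each = length(idxv)) / ct
    Y <- ict[, use, drop = FALSE] / ct
  }
  if (!any(ok)) abort_dynapet("No usable voxels in the mask.")
  slope_v <- intercept_v <- rep(NA_real_, length(idxv))
  Xo <- X[ok, , drop = FALSE]; Yo <- Y[ok, , drop = FALSE]
  mX <- rowMeans(Xo); mY <- rowMeans(Yo)
  Xc <- Xo - mX; Yc <- Yo - mY
  sxx <- rowSums(Xc^2)
  bad_x <- sxx <= 0
  sl <- rowSums(Xc * Yc) / sxx
  sl[bad_x] <- NA_real_
  slope_v[ok] <- sl
  intercept_v[ok] <- mY - sl * mX
  keep <- ok & is.finite(slope_v)
  slope3 <- intercept3 <- array(0, d[1:3])
  outmask <- array(FALSE, d[1:3])
  slope3[idxv[keep]] <- slope_v[keep]
  intercept3[idxv[keep]] <- intercept_v[keep]
  outmask[idxv[keep]] <- TRUE
  new_parametric_map(slope3, intercept3, outmask, tstar_min, kind)
}
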