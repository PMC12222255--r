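#' Area under a time-activity curve
#'
#' Trapezoid rule over frame mid-times with a zero anchor at t = 0,
#' reported in (curve units) x minutes.
#'
#' @param tac A `pet_tac` (or any data frame with `mid_s` and `mean`).
#' @return AUC in units x min.
#' @export
auc_trapezoid <- function(tac) {
  if (nrow(tac) < 2L) abort_dynapet("AUC needs at least 2 points.")
  x <- c(0, tac$mid_s) / 60
  y <- c(0, tac$mean)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Percent bias relative to a reference
#'
#' `100 * (x - ref) / ref`.
#'
#' @param x Measured value(s).
#' @param ref Reference value(s); must be non-zero.
#' @return Percent bias.
#' @examples
#' percent_bias(0.19, 0.20) # -5
#' @export
percent_bias <- function(x, ref) {
  if (any(ref == 0)) abort_dynapet("Reference must be non-zero.")
  100 * (x - ref) / ref
}

#' Root-mean-square error between two volumes
#'
#' @param img,ref Arrays of identical shape.
#' @param mask Optional logical array restricting the comparison (default:
#'   whole volume).
#' @return RMSE in image units.
#' @export
rmse_image <- function(img, ref, mask = NULL) {
  if (!identical(dim(img), dim(ref))) abort_dynapet("Shapes must match.")
  d2 <- (img - ref)^2
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(img))
    if (!sum(mask)) abort_dynapet("Mask is empty.")
    d2 <- d2[mask]
  }
  sqrt(mean(d2))
}

# separable Gaussian filter with replicate ("nearest") edge padding;
# kernel radius follows the scipy/scikit-image convention
gauss_kernel <- function(sigma, truncate = 3.5) {
  r <- as.integer(sigma * truncate + 0.5)
  if (r < 1L) return(1)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

gauss_filter3 <- function(vol, sigma, truncate = 3.5) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  out <- vol
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      out <- sep_conv3_cpp(out, gauss_kernel(sigma[ax], truncate), ax)
    }
  }
  out
}

#' Structural similarity index between two volumes
#'
#' Mean SSIM with a Gaussian weighting window (sigma 1.5, truncated at 3.5
#' sigma, population statistics), matching the common reference
#' implementation: local means/variances/covariance by Gaussian filtering
#' with replicate edge padding, the SSIM map averaged after cropping the
#' filter radius at each border. Window and stabilisation parameters are
#' recorded on the result.
#'
#' @param img,ref 3D arrays of identical shape.
#' @param sigma Gaussian window sigma in voxels (default 1.5).
#' @param K1,K2 Stabilisation constants (defaults 0.01, 0.03).
#' @param data_range Dynamic range L; default `max(ref)` (recorded).
#' @return SSIM in \[-1, 1\] with a `params` attribute.
#' @export
ssim_image <- function(img, ref, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       data_range = NULL) {
  if (!identical(dim(img), dim(ref))) abort_dynapet("Shapes must match.")
  data_range <- data_range %||% max(ref)
  if (!is.finite(data_range) || data_range <= 0) {
    abort_dynapet("`data_range` must resolve to a positive number.")
  }
  truncate <- 3.5
  r <- as.integer(sigma * truncate + 0.5)
  if (any(dim(img) <= 2L * r)) {
    abort_dynapet("Volume too small for the SSIM window.")
  }
  G <- function(v) gauss_filter3(v, sigma, truncate)
  ux <- G(img); uy <- G(ref)
  vx <- G(img * img) - ux * ux
  vy <- G(ref * ref) - uy * uy
  vxy <- G(img * ref) - ux * uy
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  d <- dim(S)
  core <- S[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)]
  structure(mean(core),
            params = list(sigma = sigma, K1 = K1, K2 = K2,
                          data_range = data_range, truncate = truncate))
}

#' Two-tailed paired t-test with a Bonferroni gate
#'
#' @param a,b Paired samples of equal length (>= 2).
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @param alpha Family significance level (default 0.01).
#' @return A tibble with `p`, `t`, `df`, `alpha_adjusted`, `significant`
#'   (`p < alpha / n_comparisons`). Zero-variance differences yield `p = 1`
#'   by convention, with a warning.
#' @export
paired_ttest_bonferroni <- function(a, b, n_comparisons = 1, alpha = 0.01) {
  if (length(a) != length(b) || length(a) < 2L) {
    abort_dynapet("Need paired samples of equal length >= 2.")
  }
  if (n_comparisons < 1) abort_dynapet("`n_comparisons` must be >= 1.")
  d <- a - b
  if (stats::sd(d) == 0) {
    warn("Zero-variance paired differences; p set to 1 by convention.")
    p <- 1; tstat <- 0
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    p <- tt$p.value; tstat <- unname(tt$statistic)
  }
  thr <- alpha / n_comparisons
  tibble(p = p, t = tstat, df = length(a) - 1L, alpha_adjusted = thr,
         significant = p < thr)
}
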