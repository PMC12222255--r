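#' Analytic arterial input-function parameters
#'
#' A tri-exponential curve with a linear rise, the standard analytic form for
#' an FDG-like arterial plasma curve:
#' `Cp(tau) = (A1 tau - A2 - A3) exp(-l1 tau) + A2 exp(-l2 tau) + A3 exp(-l3 tau)`
#' with `tau = (t - t0)` in minutes and `Cp = 0` before the appearance time
#' `t0`. Amplitudes are kBq/ml (A1 in kBq/ml/min); rates are min^-1 and must
#' satisfy `l1 > l2 > l3 >= 0`.
#'
#' @param A1,A2,A3 Amplitudes (A1 kBq/ml/min, A2/A3 kBq/ml).
#' @param l1,l2,l3 Decay rates in min^-1, strictly ordered `l1 > l2 > l3 >= 0`.
#' @param t0_s Appearance delay in seconds.
#' @return A list of class `if_params`.
#' @export
if_params <- function(A1 = 300, A2 = 15, A3 = 12,
                      l1 = 4.1, l2 = 0.12, l3 = 0.0105, t0_s = 20) {
  if (!(l1 > l2 && l2 > l3 && l3 >= 0)) {
    abort_dynapet("Rates must satisfy l1 > l2 > l3 >= 0.")
  }
  if (any(!is.finite(c(A1, A2, A3, t0_s)))) abort_dynapet("Parameters must be finite.")
  structure(list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3,
                 t0_s = t0_s), class = "if_params")
}

#' Evaluate the analytic input function on a time grid
#'
#' @param params An [if_params()].
#' @param t_s Ascending time grid in seconds.
#' @return A tibble of class `blood_curve` with columns `t_s`, `value`
#'   (kBq/ml). Errors if the parameters produce a negative curve anywhere on
#'   the grid.
#' @export
feng_if <- function(params, t_s) {
  stopifnot(inherits(params, "if_params"))
  if (any(diff(t_s) <= 0) || any(t_s < 0)) {
    abort_dynapet("`t_s` must be ascending and >= 0.")
  }
  tau <- pmax(t_s - params$t0_s, 0) / 60
  v <- (params$A1 * tau - params$A2 - params$A3) * exp(-params$l1 * tau) +
    params$A2 * exp(-params$l2 * tau) + params$A3 * exp(-params$l3 * tau)
  v[t_s < params$t0_s] <- 0
  if (any(v < -1e-9)) {
    abort_dynapet("Input-function parameters yield a negative curve on the grid.")
  }
  out <- tibble(t_s = as.numeric(t_s), value = pmax(v, 0))
  class(out) <- c("blood_curve", class(out))
  out
}

#' Phantom region
#'
#' An ellipsoidal region with either tissue kinetics (`model = "1tcm"` or
#' `"2tcm_irr"` with a [kinetic_params()]) or a blood-pool flag
#' (`model = "blood"`, no tissue kinetics). The liver may take the dual
#' blood input (`input = "dual"`).
#'
#' @param name Region label.
#' @param center_mm,semiaxes_mm Length-3 numerics (mm); semi-axes > 0.
#' @param model `"1tcm"`, `"2tcm_irr"` or `"blood"`.
#' @param kinetics A [kinetic_params()] for tissue models; must be `NULL`
#'   for blood pools.
#' @param input `"arterial"` (default) or `"dual"` (dispersed portal
#'   admixture, for the liver).
#' @return A list of class `phantom_region`.
#' @export
region <- function(name, center_mm, semiaxes_mm,
                   model = c("2tcm_irr", "1tcm", "blood"),
                   kinetics = NULL, input = c("arterial", "dual")) {
  model <- match.arg(model)
  input <- match.arg(input)
  if (any(semiaxes_mm <= 0)) abort_dynapet("Semi-axes must be > 0.")
  if (model == "blood" && !is.null(kinetics)) {
    abort_dynapet("Blood-pool regions carry no tissue kinetics.")
  }
  if (model != "blood" && !inherits(kinetics, "kinetic_params")) {
    abort_dynapet("Tissue regions need `kinetics` of class kinetic_params.")
  }
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 semiaxes_mm = as.numeric(semiaxes_mm), model = model,
                 kinetics = kinetics, input = input),
            class = "phantom_region")
}

#' Phantom specification
#'
#' @param grid Length-3 integer voxel grid (each >= 8).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param regions List of [region()]s; later regions overwrite earlier ones
#'   where they overlap (last-writer-wins layering, used e.g. for a necrotic
#'   lesion core inside a lesion).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, voxel_size_mm, regions) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L)) {
    abort_dynapet("`grid` must be three integers >= 8.")
  }
  if (any(voxel_size_mm <= 0)) abort_dynapet("Voxel size must be positive.")
  if (!length(regions)) abort_dynapet("Need at least one region.")
  stopifnot(all(vapply(regions, inherits, TRUE, "phantom_region")))
  structure(list(grid = grid, voxel_size_mm = as.numeric(voxel_size_mm),
                 regions = setNames(regions, vapply(regions, `[[`, "", "name"))),
            class = "phantom_spec")
}

#' Region masks of a phantom
#'
#' @param phantom A [phantom_spec()].
#' @return Named list of 3D logical arrays, one per region, with
#'   last-writer-wins layering already applied (a voxel belongs to the last
#'   region that covers it).
#' @export
region_masks <- function(phantom) {
  g <- phantom$grid
  vs <- phantom$voxel_size_mm
  cx <- (seq_len(g[1]) - 0.5) * vs[1]
  cy <- (seq_len(g[2]) - 0.5) * vs[2]
  cz <- (seq_len(g[3]) - 0.5) * vs[3]
  owner <- array(0L, g)
  raw <- vector("list", length(phantom$regions))
  for (i in seq_along(phantom$regions)) {
    r <- phantom$regions[[i]]
    dx2 <- ((cx - r$center_mm[1]) / r$semiaxes_mm[1])^2
    dy2 <- ((cy - r$center_mm[2]) / r$semiaxes_mm[2])^2
    dz2 <- ((cz - r$center_mm[3]) / r$semiaxes_mm[3])^2
    m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    raw[[i]] <- m
    owner[m] <- i
  }
  out <- lapply(seq_along(raw), function(i) raw[[i]] & (owner == i))
  setNames(out, names(phantom$regions))
}

#' Render a noiseless dynamic image from a phantom
#'
#' Each region's continuous concentration curve is generated on a uniform
#' 1-s grid from its compartment model (blood pools carry the blood curve
#' itself; `input = "dual"` regions use [dual_input()]), then averaged over
#' each frame interval. Background voxels are 0.
#'
#' @param phantom A [phantom_spec()].
#' @param if_par An [if_params()] or a precomputed `blood_curve` covering
#'   the schedule.
#' @param schedule A [frame_schedule()].
#' @param calibration A [counts_calibration()] attached to the output.
#' @param dual_fa,dual_ka Dual-input parameters for `input = "dual"` regions.
#' @return A noiseless [dynamic_image()].
#' @export
render_dynamic <- function(phantom, if_par, schedule,
                           calibration = counts_calibration(),
                           dual_fa = 0.25, dual_ka = 1) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(schedule, "frame_schedule"))
  t_end <- max(schedule$end_s)
  t_s <- seq(0, t_end, by = 1)
  cp <- if (inherits(if_par, "if_params")) feng_if(if_par, t_s)
        else {
          if (max(if_par$t_s) < t_end) {
            abort_dynapet("Blood curve must cover the schedule.")
          }
          tibble(t_s = t_s,
                 value = stats::approx(if_par$t_s, if_par$value, t_s, rule = 2)$y)
        }
  cpv <- cp$value
  cdual <- NULL
  masks <- region_masks(phantom)
  nF <- nrow(schedule)
  flat <- matrix(0, prod(phantom$grid), nF)
  for (nm in names(phantom$regions)) {
    r <- phantom$regions[[nm]]
    curve <- if (r$model == "blood") {
      cpv
    } else {
      inp <- if (r$input == "dual") {
        if (is.null(cdual)) cdual <- dual_input(cpv, t_s, dual_fa, dual_ka)
        cdual
      } else cpv
      if (r$model == "2tcm_irr") model_tac_2tcm_irr(r$kinetics, inp, t_s)
      else model_tac_1tcm(r$kinetics, inp, t_s)
    }
    fv <- frame_average(curve, t_s, schedule)
    idx <- which(masks[[nm]])
    if (length(idx)) flat[idx, ] <- rep(fv, each = length(idx))
  }
  dynamic_image(array(flat, c(phantom$grid, nF)), phantom$voxel_size_mm,
                schedule, calibration)
}

#' Expected detected counts of a dynamic image
#'
#' `counts[v, f] = conc[v, f] * voxel_volume_ml * duration_s[f] *
#' sensitivity * dose_fraction`, the image-space counts proxy through which
#' Poisson noise, dose thinning and bootstrap resampling are applied.
#'
#' @param image A [dynamic_image()].
#' @return 4D non-negative numeric array of expected counts.
#' @export
expected_counts <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  cal <- image$calibration
  scale_f <- voxel_volume_ml(image) * image$schedule$dur_s *
    cal$sensitivity * cal$dose_fraction
  d <- dim(image$voxels)
  out <- image$voxels * rep(scale_f, each = prod(d[1:3]))
  if (any(out < 0)) abort_dynapet("Negative expected counts.")
  out
}

#' Convert a counts array back to an activity-concentration image
#'
#' Inverse of [expected_counts()] under the stated calibration; used to turn
#' noisy/thinned counts into the concentration image a scanner would
#' reconstruct (thinned data are divided by their reduced dose fraction, so
#' low-dose images are unbiased in the mean).
#'
#' @param counts 4D counts array.
#' @param template A [dynamic_image()] providing geometry, schedule and
#'   sensitivity.
#' @param dose_fraction Dose fraction of the counts (defaults to the
#'   template's).
#' @return A [dynamic_image()] with the stated `dose_fraction` recorded.
#' @export
counts_to_image <- function(counts, template,
                            dose_fraction = template$calibration$dose_fraction) {
  cal <- counts_calibration(template$calibration$sensitivity, dose_fraction)
  scale_f <- voxel_volume_ml(template) * template$schedule$dur_s *
    cal$sensitivity * cal$dose_fraction
  d <- dim(counts)
  conc <- counts / rep(scale_f, each = prod(d[1:3]))
  dynamic_image(conc, template$voxel_size_mm, template$schedule, cal)
}

#' Sample Poisson count noise
#'
#' Each voxel-frame entry is drawn `Poisson(expected)`. Deterministic for a
#' fixed seed; the global RNG state is untouched.
#'
#' @param counts 4D array of non-negative expected counts.
#' @param seed Integer seed.
#' @return Integer-valued 4D array of observed counts.
#' @export
add_poisson_noise <- function(counts, seed) {
  if (any(counts < 0)) abort_dynapet("Expected counts must be >= 0.")
  d <- dim(counts)
  out <- with_local_seed(seed, stats::rpois(length(counts), counts))
  array(as.numeric(out), d)
}

#' Binomial dose-reduction thinning of observed counts
#'
#' Emulates event-level random splitting of a scan's counts: each entry `n`
#' becomes `Binomial(n, factor)`. With `complementary = TRUE` the complement
#' `n - thinned` is returned too; thinned + complement always reconstructs
#' the original exactly.
#'
#' @param counts 4D array of non-negative integer counts.
#' @param factor Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @param complementary Return the complement split as well?
#' @return The thinned array, or a list `(thinned, complement)` when
#'   `complementary = TRUE`.
#' @export
thin_counts <- function(counts, factor, seed, complementary = FALSE) {
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    abort_dynapet("Thinning `factor` must lie in (0, 1].")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_dynapet("Counts must be non-negative integers.")
  }
  d <- dim(counts)
  if (factor == 1) {
    thin <- counts
  } else {
    thin <- array(as.numeric(
      with_local_seed(seed, stats::rbinom(length(counts), as.integer(round(counts)), factor))
    ), d)
  }
  if (complementary) list(thinned = thin, complement = counts - thin) else thin
}

#' Poisson bootstrap replicates of a counts array
#'
#' Image-space analog of list-mode bootstrapping: each replicate entry is
#' drawn `Poisson(observed count)`, replicates mutually independent given
#' the seed stream.
#'
#' @param counts 4D non-negative counts array.
#' @param B Number of replicates (default 10).
#' @param seed Integer seed.
#' @return List of `B` replicate count arrays.
#' @export
bootstrap_counts <- function(counts, B = 10, seed = 1) {
  if (B < 1) abort_dynapet("`B` must be >= 1.")
  if (any(counts < 0)) abort_dynapet("Counts must be >= 0.")
  d <- dim(counts)
  lapply(seq_len(B), function(b) {
    array(as.numeric(
      with_local_seed(derive_seed(seed, b), stats::rpois(length(counts), counts))
    ), d)
  })
}

#' Deterministic seed fan-out
#'
#' Children of a master seed: `derive_seed(seed, k)` is a fixed affine map
#' modulo the Mersenne prime 2^31 - 1, so every stochastic stage of a
#' pipeline gets an independent, reproducible stream from one master seed.
#'
#' @param seed Master integer seed.
#' @param index Non-negative child index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((((as.double(seed) %% 2147483647) * 48271) + index * 8191 + 1) %% 2147483647)
}

#' Built-in demonstration phantom
#'
#' A torso-like voxel phantom with liver (dual blood input), lung, psoas
#' muscle, thalamus, descending aorta and right ventricle blood pools, and a
#' lesion with a low-uptake necrotic core. Kinetic parameters are stored as
#' ground truth alongside the geometry.
#'
#' @param size `"small"` (32^3 voxels of 4 mm) or `"demo"` (40^3).
#' @return A list of class `phantom_bundle`: `phantom` ([phantom_spec()]),
#'   `if_params`, `meta` ([subject_meta()]), and `truth`, a tibble of the
#'   per-region generating parameters with derived `Ki`/`VT`.
#' @export
default_phantom <- function(size = c("small", "demo")) {
  size <- match.arg(size)
  n <- switch(size, small = 32L, demo = 40L)
  vs <- 4
  s <- n * vs / 128  # geometry defined on a 128-mm reference cube
  kp <- list(
    body     = kinetic_params(0.04, 0.35, 0.004, vB = 0.03, delay_s = 6),
    liver    = kinetic_params(0.60, 0.90, 0.02, vB = 0.15, delay_s = 4),
    lung     = kinetic_params(0.10, 0.40, 0.01, vB = 0.15, delay_s = 1),
    muscle   = kinetic_params(0.05, 0.25, 0.02, vB = 0.02, delay_s = 6),
    thalamus = kinetic_params(0.09, 0.20, 0.06, vB = 0.04, delay_s = 3),
    # the lesion is reversible (glutamine-like): VT = K1/k2 is its readout,
    # with a low-VT necrotic core
    lesion   = kinetic_params(0.35, 0.175, 0, vB = 0.05, delay_s = 5),
    lesion_core = kinetic_params(0.08, 0.16, 0, vB = 0.02, delay_s = 5)
  )
  regions <- list(
    # torso-like soft-tissue background listed first: organ regions
    # overwrite it, and every slice contains tissue (as in whole-body data)
    region("body", c(64, 64, 64) * s, c(62, 62, 63) * s, "2tcm_irr", kp$body),
    region("liver", c(40, 44, 40) * s, c(24, 20, 20) * s, "2tcm_irr",
           kp$liver, input = "dual"),
    region("lung", c(88, 44, 44) * s, c(18, 16, 20) * s, "2tcm_irr", kp$lung),
    region("muscle", c(30, 96, 40) * s, c(14, 18, 20) * s, "2tcm_irr", kp$muscle),
    region("thalamus", c(96, 96, 88) * s, c(8, 8, 8) * s, "2tcm_irr", kp$thalamus),
    region("descending_aorta", c(64, 80, 64) * s, c(6, 6, 40) * s, "blood"),
    region("right_ventricle", c(92, 16, 60) * s, c(9, 9, 9) * s, "blood"),
    region("lesion", c(30, 20, 80) * s, c(12, 12, 12) * s, "1tcm", kp$lesion),
    region("lesion_core", c(30, 20, 80) * s, c(5, 5, 5) * s, "1tcm",
           kp$lesion_core)
  )
  truth <- purrr::map_dfr(names(kp), function(nm) {
    p <- kp[[nm]]
    tibble(region = nm, K1 = p$K1, k2 = p$k2, k3 = p$k3, vB = p$vB,
           delay_s = p$delay_s,
           Ki = ki_macro(p$K1, p$k2, p$k3),
           VT = vt_macro(p$K1, p$k2))
  })
  structure(list(
    phantom = phantom_spec(c(n, n, n), c(vs, vs, vs), regions),
    if_params = if_params(),
    meta = subject_meta(370, 74, tracer = "FDG"),
    truth = truth
  ), class = "phantom_bundle")
}

#' Simulate a late static acquisition from a phantom bundle
#'
#' Renders the phantom over a single late frame (10 minutes by default,
#' emulating a delayed static image), applies Poisson count noise at the
#' stated calibration, and returns the reconstructed static image used to
#' build denoiser training pairs.
#'
#' @param bundle A [default_phantom()] bundle.
#' @param start_s,end_s Acquisition window in seconds (default 3000-3600).
#' @param seed Integer seed for the count noise.
#' @param calibration A [counts_calibration()].
#' @return A single-frame [dynamic_image()].
#' @export
simulate_static_image <- function(bundle, start_s = 3000, end_s = 3600,
                                  seed = 1,
                                  calibration = counts_calibration()) {
  sched <- frame_schedule(start_s, end_s)
  clean <- render_dynamic(bundle$phantom, bundle$if_params, sched,
                          calibration = calibration)
  obs <- add_poisson_noise(expected_counts(clean), seed)
  counts_to_image(obs, clean)
}
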