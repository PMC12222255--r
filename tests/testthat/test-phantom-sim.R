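test_that("the analytic input function is causal, non-negative, single-peaked", {
  t_s <- grid_3600()
  cp <- default_cp()
  p <- if_params()
  expect_true(all(cp$value[t_s < p$t0_s] == 0))
  expect_true(all(cp$value >= 0))
  # peak from a 10x denser grid agrees within one coarse step
  tf <- seq(0, 300, by = 0.1)
  cpf <- feng_if(p, tf)
  expect_lt(abs(tf[which.max(cpf$value)] - cp$t_s[which.max(cp$value)]), 1 + 1e-9)
  # after the peak and early washout the curve decays monotonically
  late <- cp$value[cp$t_s > 600]
  expect_true(all(diff(late) <= 1e-9))
  expect_error(if_params(l1 = 0.1, l2 = 0.2, l3 = 0.01),
               class = "dynapet_error")
})

test_that("render_dynamic frame values are exact time averages", {
  sch <- parse_schedule_spec(list(c(4, 30)))
  bundle <- demo_bundle()
  # constant blood curve: every blood-pool frame equals the constant
  cp_const <- tibble::tibble(t_s = seq(0, 120, 1), value = 7)
  class(cp_const) <- c("blood_curve", class(cp_const))
  img <- render_dynamic(bundle$phantom, cp_const, sch)
  da <- region_masks(bundle$phantom)$descending_aorta
  expect_equal(roi_extract(img, da)$mean, rep(7, 4), tolerance = 1e-12)

  # linear ramp a*t: frame average is exactly a*(start+end)/2
  a <- 0.01
  cp_ramp <- tibble::tibble(t_s = seq(0, 120, 1), value = a * seq(0, 120, 1))
  class(cp_ramp) <- c("blood_curve", class(cp_ramp))
  img2 <- render_dynamic(bundle$phantom, cp_ramp, sch)
  expect_equal(roi_extract(img2, da)$mean, a * (sch$start_s + sch$end_s) / 2,
               tolerance = 1e-10)
})

test_that("rendered 2-TCM frames match a dense quadrature oracle within 0.1%", {
  sch <- sched_39()
  bundle <- demo_bundle()
  img <- clean_dynamic()
  thal <- region_masks(bundle$phantom)$thalamus
  got <- roi_extract(img, thal)$mean
  # oracle: model curve on a 0.2-s grid, frame averages by dense trapezoid
  tf <- seq(0, 3600, by = 0.2)
  cpf <- feng_if(bundle$if_params, tf)
  p <- bundle$phantom$regions$thalamus$kinetics
  curvef <- model_tac_2tcm_irr(p, cpf$value, tf)
  oracle <- dynapet:::frame_average(curvef, tf, sch)
  # peak-normalized: tiny frames during the input rise carry the grid error
  expect_lt(max(abs(got - oracle)) / max(oracle), 1e-3)
})

test_that("render_dynamic is linear in the input-function amplitude", {
  sch <- parse_schedule_spec(list(c(3, 60)))
  bundle <- demo_bundle()
  p1 <- bundle$if_params
  p2 <- if_params(A1 = 2 * p1$A1, A2 = 2 * p1$A2, A3 = 2 * p1$A3,
                  l1 = p1$l1, l2 = p1$l2, l3 = p1$l3, t0_s = p1$t0_s)
  i1 <- render_dynamic(bundle$phantom, p1, sch)
  i2 <- render_dynamic(bundle$phantom, p2, sch)
  expect_equal(i2$voxels, 2 * i1$voxels, tolerance = 1e-10)
})

test_that("expected counts scale with duration, dose fraction and activity", {
  sch <- parse_schedule_spec(list(c(1, 10), c(1, 20)))
  vox <- array(3, c(4, 4, 4, 2))
  img <- dynamic_image(vox, c(4, 4, 4), sch, counts_calibration(60, 1))
  cnt <- expected_counts(img)
  expect_equal(cnt[1, 1, 1, 2], 2 * cnt[1, 1, 1, 1])  # duration doubles
  half <- dynamic_image(vox, c(4, 4, 4), sch, counts_calibration(60, 0.5))
  expect_equal(expected_counts(half), cnt / 2)
  zero <- dynamic_image(vox * 0, c(4, 4, 4), sch, counts_calibration(60, 1))
  expect_true(all(expected_counts(zero) == 0))
  # explicit value: 3 kBq/ml * 0.064 ml * 10 s * 60 counts/(kBq s)
  expect_equal(cnt[1, 1, 1, 1], 3 * 0.064 * 10 * 60)
})

test_that("Poisson noise has the right mean, respects zeros, is seeded", {
  lam <- array(0, c(2, 2, 1, 1))
  expect_true(all(add_poisson_noise(lam, 1) == 0))
  lam50 <- array(50, c(10, 10, 10, 10))
  draws <- add_poisson_noise(lam50, 99)
  se <- sqrt(50 / length(lam50))
  expect_lt(abs(mean(draws) - 50), 3 * se)
  expect_identical(add_poisson_noise(lam50, 5), add_poisson_noise(lam50, 5))
  expect_error(add_poisson_noise(array(-1, c(1, 1, 1, 1)), 1),
               class = "dynapet_error")
})

test_that("binomial thinning conserves counts with its complement", {
  set.seed(1)
  counts <- array(as.numeric(rpois(4^4, 40)), c(4, 4, 4, 4))
  for (f in c(0.5, 0.1)) {
    parts <- thin_counts(counts, f, seed = 3, complementary = TRUE)
    expect_identical(parts$thinned + parts$complement, counts)
    expect_true(all(parts$thinned >= 0))
  }
  expect_identical(thin_counts(counts, 1, seed = 2), counts)
  expect_error(thin_counts(counts, 0, seed = 1), class = "dynapet_error")
  expect_error(thin_counts(counts + 0.5, 0.5, seed = 1),
               class = "dynapet_error")
})

test_that("thinning means and composition follow the binomial law", {
  n0 <- 1000L
  counts <- array(n0, c(10, 10, 10, 10))  # 1e4 entries
  th <- thin_counts(counts, 0.5, seed = 8)
  se <- sqrt(n0 * 0.25 / length(counts))
  expect_lt(abs(mean(th) - 500), 3 * se)
  # thinning by f1 then f2 behaves as one Binomial(n, f1 f2)
  t1 <- thin_counts(counts, 0.4, seed = 21)
  t12 <- thin_counts(t1, 0.5, seed = 22)
  exp_mean <- n0 * 0.2
  se2 <- sqrt(n0 * 0.2 * 0.8 / length(counts))
  expect_lt(abs(mean(t12) - exp_mean), 3 * se2)
})

test_that("bootstrap replicates are Poisson-centred on the observed counts", {
  counts <- array(50, c(5, 5, 2, 2))
  reps <- bootstrap_counts(counts, B = 10, seed = 4)
  expect_length(reps, 10L)
  expect_identical(bootstrap_counts(counts, B = 10, seed = 4), reps)
  # replicate mean of a single entry over many replicates
  one <- array(50, c(1, 1, 1, 1))
  many <- bootstrap_counts(one, B = 5000, seed = 6)
  m <- mean(vapply(many, function(x) x[1], 0))
  expect_lt(abs(m - 50), 3 * sqrt(50 / 5000))
})

test_that("relative ROI noise scales as one over root counts across doses", {
  # ROI of 100 voxels at constant concentration; dose ladder spanning 100x
  sch <- parse_schedule_spec(list(c(1, 10)))
  vox <- array(5, c(5, 5, 4, 1))
  doses <- c(1, 0.3, 0.1, 0.03, 0.01)
  rel_sd <- vapply(seq_along(doses), function(i) {
    f <- doses[i]
    img <- dynamic_image(vox, c(4, 4, 4), sch,
                         counts_calibration(dose_fraction = f))
    lam <- expected_counts(img)
    means <- vapply(1:60, function(r) {
      obs <- add_poisson_noise(lam, derive_seed(700 + i, r))
      mean(counts_to_image(obs, img)$voxels)
    }, 0)
    stats::sd(means) / mean(means)
  }, 0)
  sch_img <- dynamic_image(vox, c(4, 4, 4), sch)
  expected <- 1 / sqrt(doses * sum(expected_counts(sch_img)))
  ratio <- rel_sd / expected
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("the built-in phantom is internally consistent", {
  b <- demo_bundle()
  expect_s3_class(b$phantom, "phantom_spec")
  expect_equal(b$phantom$grid, rep(32L, 3))
  expect_gte(length(b$phantom$regions), 7L)
  masks <- region_masks(b$phantom)
  expect_true(all(vapply(masks, sum, 0) > 0))
  # layering: the core owns its voxels exclusively
  expect_equal(sum(masks$lesion & masks$lesion_core), 0L)
  # stored ground-truth macros match the formulas
  tr <- b$truth
  expect_equal(tr$Ki, tr$K1 * tr$k3 / (tr$k2 + tr$k3))
  expect_equal(tr$VT, tr$K1 / tr$k2)
  # necrotic core is colder than the shell in late noiseless frames
  img <- clean_dynamic()
  late <- img$voxels[, , , 39]
  expect_lt(median(late[masks$lesion_core]), median(late[masks$lesion]))
  expect_error(default_phantom("huge"))
})

test_that("the full-dose demo phantom has roughly 1e4 counts per ml in early frames", {
  img <- clean_dynamic()
  cnt <- expected_counts(img)
  da <- region_masks(demo_bundle()$phantom)$descending_aorta
  # counts per ml of aorta in the early 5-s frames around the IF peak
  f <- which.max(roi_extract(img, da)$mean[1:12])
  per_ml <- sum(cnt[, , , f][da]) / (sum(da) * prod(img$voxel_size_mm) / 1000)
  expect_gt(per_ml, 2e3)
  expect_lt(per_ml, 5e4)
})
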