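test_that("schedule parsing expands run-length specs into contiguous frames", {
  s <- sched_39()
  expect_equal(nrow(s), 39L)
  expect_equal(max(s$end_s), 3600)
  expect_equal(s$start_s[1], 0)
  expect_equal(s$start_s[-1], s$end_s[-39])
  expect_equal(s$mid_s, (s$start_s + s$end_s) / 2)

  s44 <- sched_44()
  expect_equal(nrow(s44), 44L)
  expect_equal(max(s44$end_s), 1800)

  one <- parse_schedule_spec(list(c(1, 60)))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start_s, one$end_s), c(0, 60))
})

test_that("schedule parsing rejects malformed specs", {
  expect_error(parse_schedule_spec(tibble::tibble(count = integer(),
                                                  duration_s = numeric())))
  expect_error(parse_schedule_spec(list(c(0, 5))), class = "dynapet_error")
  expect_error(parse_schedule_spec(list(c(3, -1))), class = "dynapet_error")
  expect_error(frame_schedule(c(0, 10), c(5, 20)), class = "dynapet_error")
  expect_error(frame_schedule(-5, 5), class = "dynapet_error")
})

test_that("total duration is additive over concatenated specs", {
  specs <- list(tibble::tibble(count = c(3, 2), duration_s = c(5, 30)),
                tibble::tibble(count = c(4, 1), duration_s = c(10, 300)))
  joint <- parse_schedule_spec(dplyr::bind_rows(specs))
  parts <- vapply(specs, function(sp) max(parse_schedule_spec(sp)$end_s), 0)
  expect_equal(max(joint$end_s), sum(parts))
})

test_that("roi_extract computes spatial mean and population SD per frame", {
  sch <- parse_schedule_spec(list(c(3, 10)))
  vox <- array(2.5, c(4, 4, 4, 3))
  img <- dynamic_image(vox, c(4, 4, 4), sch)
  mask <- array(TRUE, c(4, 4, 4))
  tac <- roi_extract(img, mask)
  expect_equal(tac$mean, rep(2.5, 3))
  expect_equal(tac$sd, rep(0, 3))
  expect_equal(tac$mid_s, sch$mid_s)

  # two-voxel mask: hand-computed mean and population SD
  vox[1, 1, 1, ] <- c(1, 2, 3)
  vox[2, 1, 1, ] <- c(3, 6, 9)
  img <- dynamic_image(vox, c(4, 4, 4), sch)
  m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, 1, 1] <- TRUE
  tac2 <- roi_extract(img, m2)
  expect_equal(tac2$mean, c(2, 4, 6))
  expect_equal(tac2$sd, c(1, 2, 3))  # population SD of {a, b} = |a - b| / 2

  # single voxel: the voxel's own series with zero spread
  m1 <- array(FALSE, c(4, 4, 4)); m1[1, 1, 1] <- TRUE
  tac1 <- roi_extract(img, m1)
  expect_equal(tac1$mean, c(1, 2, 3))
  expect_equal(tac1$sd, rep(0, 3))

  expect_error(roi_extract(img, array(FALSE, c(4, 4, 4))),
               class = "dynapet_error")
  expect_error(roi_extract(img, array(TRUE, c(3, 4, 4))),
               class = "dynapet_error")
})

test_that("mask TAC equals the mean of its single-voxel TACs", {
  set.seed(7)
  sch <- parse_schedule_spec(list(c(4, 15)))
  vox <- array(runif(5 * 5 * 5 * 4), c(5, 5, 5, 4))
  img <- dynamic_image(vox, c(4, 4, 4), sch)
  mask <- array(runif(125) < 0.3, c(5, 5, 5))
  mask[1, 1, 1] <- TRUE
  tac <- roi_extract(img, mask)
  singles <- sapply(which(mask), function(i) {
    m <- array(FALSE, c(5, 5, 5)); m[i] <- TRUE
    roi_extract(img, m)$mean
  })
  expect_equal(tac$mean, rowMeans(singles))
})

test_that("threshold_voi keeps voxels at or above the fractional maximum", {
  v <- array(1, c(8, 8, 8))
  parent <- array(TRUE, c(8, 8, 8))
  expect_equal(threshold_voi(v, parent, 0.6), parent)  # uniform: all at max

  v[3, 3, 3] <- 10
  m <- threshold_voi(v, parent, 0.6)
  expect_equal(sum(m), 1L)
  expect_true(m[3, 3, 3])

  # boundary inclusive: {10, 6, 5.9} at fraction 0.6 keeps {10, 6}
  v2 <- array(0, c(8, 8, 8))
  v2[1, 1, 1] <- 10; v2[2, 1, 1] <- 6; v2[3, 1, 1] <- 5.9
  p2 <- v2 > 0
  m2 <- threshold_voi(v2, p2, 0.6)
  expect_equal(which(m2), which(v2 >= 6))

  expect_error(threshold_voi(array(0, c(8, 8, 8)), parent, 0.6),
               class = "dynapet_error")
  expect_error(threshold_voi(v, parent, 1.2), class = "dynapet_error")
})

test_that("threshold_voi is monotone in the fraction", {
  set.seed(3)
  v <- array(runif(512), c(8, 8, 8))
  parent <- array(TRUE, c(8, 8, 8))
  fr <- c(0.2, 0.4, 0.6, 0.8, 1)
  masks <- lapply(fr, function(f) threshold_voi(v, parent, f))
  for (i in seq_len(length(fr) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))  # higher fraction nests
  }
})

test_that("SUV scaling follows dose-per-body-weight and round-trips", {
  sch <- parse_schedule_spec(list(c(2, 30)))
  tac <- dynapet:::new_tac(sch$mid_s, c(5, 0), c(0.5, 0), "kBq/ml")
  meta <- subject_meta(370, 74)
  suv <- suv_scale(tac, meta)
  expect_equal(suv$mean, c(1, 0))  # 5 kBq/ml / (370000 kBq / 74000 g)
  expect_equal(suv$units, rep("SUV", 2))
  back <- suv$mean * (meta$injected_dose_MBq * 1000) / (meta$weight_kg * 1000)
  expect_equal(back, tac$mean, tolerance = 1e-12)
  expect_error(subject_meta(0, 74), class = "dynapet_error")
})

test_that("NIfTI + sidecar and CSV round trips are lossless", {
  dir <- withr::local_tempdir()
  sch <- parse_schedule_spec(list(c(2, 5), c(1, 20)))
  set.seed(11)
  vox <- array(rnorm(8 * 8 * 8 * 3)^2, c(8, 8, 8, 3))
  img <- dynamic_image(vox, c(4, 4, 2), sch, counts_calibration(55, 0.5))
  stem <- file.path(dir, "dyn")
  write_dynamic_image(img, stem)
  back <- read_dynamic_image(stem)
  expect_identical(back$voxels, vox)
  expect_equal(back$voxel_size_mm, c(4, 4, 2))
  expect_equal(back$schedule$start_s, sch$start_s)
  expect_equal(back$schedule$end_s, sch$end_s)
  expect_equal(back$calibration$sensitivity, 55)
  expect_equal(back$calibration$dose_fraction, 0.5)

  # frame-count mismatch in the sidecar is refused
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  side$frames <- side$frames[1:2, ]
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_dynamic_image(stem), class = "dynapet_error")

  tac <- roi_extract(img, array(TRUE, c(8, 8, 8)))
  tac_path <- file.path(dir, "tac.csv")
  write_tac(tac, tac_path)
  tac2 <- read_tac(tac_path)
  expect_equal(tac2$mid_s, tac$mid_s)
  expect_equal(tac2$mean, tac$mean)
  expect_equal(tac2$units, tac$units)
})
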