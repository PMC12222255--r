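# a tiny volume + bank for structural tests (no real training needed)
tiny_bank <- function(factors = c(0.5, 0.1), seed = 2) {
  cfg <- net_config(depth = 1, base_channels = 4)
  levels <- lapply(seq_along(factors), function(i) {
    list(level = count_level(factors[i], ref_total_counts = 10^(6 - i)),
         model = dynapet:::unet_init(cfg, seed = seed + i),
         history = tibble::tibble(epoch = 1, train_loss = 1, val_loss = 1))
  })
  structure(list(levels = levels, net_cfg = cfg,
                 train_cfg = train_config()), class = "denoiser_bank")
}

test_that("network gradients match finite differences", {
  set.seed(1)
  cfg <- net_config(depth = 1, base_channels = 2)
  m <- dynapet:::unet_init(cfg, seed = 3)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  t <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fw <- dynapet:::unet_fwd(m, x, training = TRUE)
  G <- dynapet:::unet_bwd(m, fw$cache, 2 * (fw$y - t) / length(t))
  loss_of <- function(mm) {
    f <- dynapet:::unet_fwd(mm, x, training = TRUE)
    mean((f$y - t)^2)
  }
  eps <- 1e-6
  for (nm in names(G)) {
    p0 <- m$params[[nm]]
    for (i in sample(length(p0), min(2, length(p0)))) {
      mp <- m; mp$params[[nm]][i] <- p0[i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- p0[i] - eps
      num <- (loss_of(mp) - loss_of(mm2)) / (2 * eps)
      expect_equal(G[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("a zeroed correction head makes the full pipeline an exact identity", {
  bank <- tiny_bank()
  # out.W and out.b are zero-initialized, so the residual net is an identity
  set.seed(6)
  frame <- array(runif(16^3, 0.5, 2), c(16, 16, 16))
  out <- denoise_frame(frame, bank, level = 1)
  expect_equal(out, frame, tolerance = 1e-12)
  # and a uniform zero frame passes through unchanged
  z <- array(0, c(16, 16, 16))
  expect_equal(denoise_frame(z, bank, level = 1), z)
})

test_that("slice normalization round-trips and flags zero-mean slices", {
  set.seed(8)
  vp <- array(runif(6 * 6 * 5), c(6, 6, 5))
  vp[, , 2] <- 0
  win <- dynapet:::slice_windows(vp)
  nw <- dynapet:::normalize_windows(win)
  expect_false(nw$usable[2])
  expect_true(all(nw$usable[-2]))
  for (k in which(nw$usable)) {
    for (c in 1:3) {
      sl <- nw$win[, , c, k]
      if (mean(win[, , c, k]) > 0) expect_equal(mean(sl), 1, tolerance = 1e-12)
    }
    expect_equal(nw$win[, , 2, k] * nw$mid_mean[k], win[, , 2, k],
                 tolerance = 1e-12)
  }
  # edge replication: the first window's leading slice is the first slice
  expect_equal(win[, , 1, 1], vp[, , 1])
  expect_equal(win[, , 3, 5], vp[, , 5])
})

test_that("training pairs cover all factors, views and the bookkeeping", {
  b <- demo_bundle()
  static_img <- simulate_static_image(b, seed = 30)
  pairs <- build_training_pairs(static_img, factors = c(1/2, 1/5, 1/10),
                                seed = 3)
  expect_length(pairs$levels, 3L)
  lev <- pairs$levels[[1]]
  expect_equal(names(lev$groups), c("transverse", "coronal", "sagittal"))
  # 3 orientations x 32 slices, minus any unusable zero-mean slices
  n_slices <- sum(vapply(lev$groups, function(g) dim(g$x)[4], 0L))
  expect_gt(n_slices, 90)
  expect_lte(n_slices, 96)
  # reference counts drop with the factor
  refs <- vapply(pairs$levels, `[[`, 0, "ref_total_counts")
  expect_true(all(diff(refs) < 0))
  expect_error(build_training_pairs(static_img, numeric(0)),
               class = "dynapet_error")
  expect_error(build_training_pairs(static_img, c(0.5, 1.5)),
               class = "dynapet_error")
})

test_that("count-statistics matching clamps, breaks ties downward, and is scale-consistent", {
  bank <- tiny_bank(factors = c(0.5, 0.1))  # refs 1e5 and 1e4
  expect_equal(as.integer(match_level(bank, 1e5)), 1L)
  expect_equal(as.integer(match_level(bank, 1e4)), 2L)
  expect_equal(as.integer(match_level(bank, 1e9)), 1L)   # clamp high
  expect_equal(as.integer(match_level(bank, 1)), 2L)     # clamp low
  # geometric midpoint is an exact log-distance tie: lower-count level wins
  expect_equal(as.integer(match_level(bank, sqrt(1e5 * 1e4))), 2L)
  expect_warning(i0 <- match_level(bank, 0))
  expect_equal(as.integer(i0), 2L)
  # multiplying counts by the level ratio moves the match by one level
  expect_equal(as.integer(match_level(bank, 3e4 * 10)), 1L)
  expect_equal(as.integer(match_level(bank, 3e4)), 2L)
})

test_that("identity-task training drives the loss toward zero deterministically", {
  # degenerate pairs with target = input: the residual net must learn to
  # keep its zero correction, so the loss collapses quickly
  set.seed(44)
  vol <- array(runif(16^3, 0.5, 1.5), c(16, 16, 16))
  sch <- parse_schedule_spec(list(c(1, 600)))
  img <- dynamic_image(array(vol, c(16, 16, 16, 1)), c(4, 4, 4), sch)
  pairs <- build_training_pairs(img, factors = 1/5, seed = 9)
  # overwrite inputs with the targets (identity task)
  pairs$levels[[1]]$groups <- lapply(pairs$levels[[1]]$groups, function(g) {
    g$x[, , 2, ] <- g$t[, , 1, ]
    g
  })
  cfg <- net_config(depth = 1, base_channels = 4)
  tc <- train_config(learning_rate = 1e-3, batch_size = 8, epochs = 4,
                     patience = 4, seed = 11)
  bank1 <- train_bank(pairs, cfg, tc)
  h1 <- bank1$levels[[1]]$history
  # the residual head starts at zero, so the identity task is solved from
  # the first step and stays solved
  expect_lt(max(h1$train_loss), 1e-10)
  # bitwise determinism of the loss history for a fixed seed
  bank2 <- train_bank(pairs, cfg, tc)
  expect_identical(h1, bank2$levels[[1]]$history)
})

test_that("training on real thinned pairs reduces the loss", {
  b <- demo_bundle()
  static_img <- simulate_static_image(b, seed = 13)
  pairs <- build_training_pairs(static_img, factors = 1/10, seed = 14)
  tc <- train_config(learning_rate = 5e-3, batch_size = 8, epochs = 15,
                     patience = 15, seed = 15)
  bank <- train_bank(pairs, net_config(depth = 2, base_channels = 4), tc)
  h <- bank$levels[[1]]$history
  expect_lt(min(h$train_loss), 0.9 * h$train_loss[1])
  # numerically exploding inputs make the loss non-finite: abort, not NaN
  bad <- pairs
  bad$levels[[1]]$groups <- lapply(bad$levels[[1]]$groups, function(g) {
    g$x <- g$x * 1e200
    g$t <- g$t * 1e200
    g
  })
  expect_error(train_bank(bad, net_config(depth = 1, base_channels = 4),
                          train_config(learning_rate = 1e-3, batch_size = 8,
                                       epochs = 2, seed = 1)),
               class = "dynapet_error")
})

test_that("frame routing uses count statistics and honors the override", {
  bank <- tiny_bank(factors = c(0.5, 0.1))
  sch <- parse_schedule_spec(list(c(2, 5), c(1, 300)))
  set.seed(3)
  vox <- array(runif(16^3 * 3, 0.5, 1.5), c(16, 16, 16, 3))
  img <- dynamic_image(vox, c(4, 4, 4), sch)
  # scale refs so the short early frames sit near the low-count level
  cnt <- expected_counts(img)
  totals <- colSums(matrix(cnt, ncol = 3))
  bank$levels[[1]]$level$ref_total_counts <- totals[3]
  bank$levels[[2]]$level$ref_total_counts <- totals[1]
  out <- denoise_dynamic(img, bank)
  lv <- attr(out, "levels")
  expect_equal(nrow(lv), 3L)
  expect_equal(lv$level, c(2L, 2L, 1L))  # early short frames -> lower counts
  expect_equal(dim(out$voxels), dim(vox))
  ov <- denoise_dynamic(img, bank, level_override = 1)
  expect_equal(attr(ov, "levels")$level, rep(1L, 3))
})

test_that("a bank serializes and reloads losslessly", {
  dir <- withr::local_tempdir()
  bank <- tiny_bank()
  write_bank(bank, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_bank(dir)
  expect_equal(length(back$levels), length(bank$levels))
  expect_equal(back$levels[[1]]$level$factor, 0.5)
  expect_equal(back$levels[[1]]$model$params, bank$levels[[1]]$model$params)
  expect_equal(back$net_cfg$depth, bank$net_cfg$depth)
})

test_that("parameter counting reports the configured architecture", {
  expect_gt(n_params(net_config()), 2e5)  # the desk-scale default
  expect_lt(n_params(net_config()), 5e5)
  expect_gt(n_params(net_config(base_channels = 32)),
            n_params(net_config(base_channels = 16)))
})
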