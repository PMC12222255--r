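#' Count level of a trained denoiser
#'
#' @param factor Count-reduction factor in (0, 1].
#' @param ref_total_counts Total counts of the training condition (> 0).
#' @return A list of class `count_level`.
#' @export
count_level <- function(factor, ref_total_counts) {
  if (factor <= 0 || factor > 1) abort_dynapet("`factor` must lie in (0, 1].")
  if (ref_total_counts <= 0) abort_dynapet("`ref_total_counts` must be > 0.")
  structure(list(factor = factor, ref_total_counts = ref_total_counts),
            class = "count_level")
}

view_perms <- list(transverse = c(1L, 2L, 3L),
                   coronal = c(1L, 3L, 2L),
                   sagittal = c(2L, 3L, 1L))

inv_perm <- function(p) order(p)

# (H, W, S) volume -> (H, W, 3, S) sliding 3-slice windows, edge-replicated
slice_windows <- function(vp) {
  d <- dim(vp)
  S <- d[3]
  arr <- array(0, c(d[1], d[2], 3, S))
  for (k in seq_len(S)) {
    arr[, , 1, k] <- vp[, , max(k - 1, 1)]
    arr[, , 2, k] <- vp[, , k]
    arr[, , 3, k] <- vp[, , min(k + 1, S)]
  }
  arr
}

# normalize each input slice by its own mean; returns the normalized
# windows, per-window middle-slice means and a usable flag (mean > 0)
normalize_windows <- function(win) {
  d <- dim(win)
  hw <- d[1] * d[2]
  m <- matrix(colMeans(matrix(win, nrow = hw)), nrow = 3)  # 3 x S
  out <- win
  for (c in 1:3) {
    mc <- m[c, ]
    pos <- mc > 0
    if (any(pos)) {
      out[, , c, pos] <- win[, , c, pos, drop = FALSE] /
        rep(mc[pos], each = hw)
    }
  }
  list(win = out, mid_mean = m[2, ], usable = m[2, ] > 0)
}

#' Build per-level training pairs from a static image
#'
#' Thins the counts of a single-frame static image at each reduction
#' factor, pairs the thinned (input) with the full-count (target) image,
#' resorts both into transverse, coronal and sagittal 2D slice sequences,
#' forms 3-slice sliding windows with edge replication, and normalizes each
#' input slice by its own mean (targets by the input middle-slice mean).
#'
#' @param static_img A single-frame [dynamic_image()].
#' @param factors Reduction factors, each in (0, 1).
#' @param seed Integer seed for the thinning draws.
#' @return A list of class `training_pairs`: one element per factor with
#'   `factor`, `ref_total_counts` and per-view sample groups.
#' @export
build_training_pairs <- function(static_img, factors, seed = 1) {
  stopifnot(inherits(static_img, "dynamic_image"))
  if (dim(static_img$voxels)[4] != 1L) {
    abort_dynapet("Training uses a single-frame static image.")
  }
  if (!length(factors)) abort_dynapet("`factors` must be non-empty.")
  if (any(factors <= 0) || any(factors >= 1)) {
    abort_dynapet("Each factor must lie in (0, 1).")
  }
  counts <- round(expected_counts(static_img))
  target_vol <- static_img$voxels[, , , 1]
  levels <- vector("list", length(factors))
  for (j in seq_along(factors)) {
    f <- factors[j]
    thin <- thin_counts(counts, f, seed = derive_seed(seed, j))
    input_img <- counts_to_image(thin, static_img,
                                 dose_fraction = static_img$calibration$dose_fraction * f)
    input_vol <- input_img$voxels[, , , 1]
    groups <- lapply(view_perms, function(p) {
      wi <- slice_windows(aperm(input_vol, p))
      wt <- slice_windows(aperm(target_vol, p))
      nw <- normalize_windows(wi)
      hw <- prod(dim(wi)[1:2])
      t_norm <- wt[, , 2, , drop = FALSE]
      pos <- nw$usable
      if (any(pos)) {
        t_norm[, , 1, pos] <- t_norm[, , 1, pos, drop = FALSE] /
          rep(nw$mid_mean[pos], each = hw)
      }
      list(x = nw$win[, , , pos, drop = FALSE],
           t = t_norm[, , , pos, drop = FALSE])
    })
    levels[[j]] <- list(factor = f, ref_total_counts = sum(thin),
                        groups = groups)
  }
  structure(list(levels = levels, seed = seed), class = "training_pairs")
}

#' Train a bank of count-level-matched denoising networks
#'
#' One network per reduction factor, minimizing the mean squared error
#' between the predicted and target middle slices. The network output is a
#' residual correction added to the input middle slice. Slices are split
#' 90/10 into train/validation with the configured seed; training stops
#' early when validation loss has not improved for `patience` epochs, and
#' the best-validation weights are kept. Deterministic given the seed.
#'
#' @param pairs A [build_training_pairs()] result.
#' @param net_cfg A [net_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses?
#' @return A list of class `denoiser_bank`: `levels` sorted by factor
#'   descending, each with its `count_level`, trained model and loss
#'   history; plus the configurations.
#' @export
train_bank <- function(pairs, net_cfg = net_config(),
                       train_cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(pairs, "training_pairs"))
  lv <- lapply(seq_along(pairs$levels), function(j) {
    lev <- pairs$levels[[j]]
    model <- train_one_level(lev, net_cfg, train_cfg,
                             seed = derive_seed(train_cfg$seed, j),
                             verbose = verbose)
    list(level = count_level(lev$factor, lev$ref_total_counts),
         model = model$model, history = model$history)
  })
  ord <- order(vapply(lv, function(l) l$level$factor, 0), decreasing = TRUE)
  structure(list(levels = lv[ord], net_cfg = net_cfg, train_cfg = train_cfg),
            class = "denoiser_bank")
}

#' @export
print.denoiser_bank <- function(x, ...) {
  cat(sprintf("<denoiser_bank> %d levels (%s params each)\n",
              length(x$levels),
              format(n_params(x$net_cfg), big.mark = ",")))
  for (l in x$levels) {
    cat(sprintf("  1/%g: ref counts %.3g, %d epochs, val loss %.3g\n",
                1 / l$level$factor, l$level$ref_total_counts,
                nrow(l$history), min(l$history$val_loss)))
  }
  invisible(x)
}

train_one_level <- function(lev, net_cfg, train_cfg, seed, verbose = FALSE) {
  groups <- lev$groups
  D <- net_cfg$depth
  groups <- lapply(groups, function(g) {
    list(x = pad_to_mult(g$x, 2^D), t = pad_to_mult(g$t, 2^D))
  })
  ns <- vapply(groups, function(g) dim(g$x)[4], 0L)
  if (sum(ns) == 0) abort_dynapet("No usable training slices at this level.")
  # 90/10 train/validation split by slice, seeded
  split <- with_local_seed(seed, lapply(ns, function(n) {
    nv <- max(1L, floor(train_cfg$val_fraction * n))
    val <- sample.int(n, nv)
    list(train = setdiff(seq_len(n), val), val = val)
  }))
  model <- unet_init(net_cfg, seed = seed)
  opt <- adam_init(model$params)
  hist <- list()
  best <- list(val = Inf, model = model, since = 0L)
  for (ep in seq_len(train_cfg$epochs)) {
    ep_losses <- c()
    order_seed <- derive_seed(seed, 1000 + ep)
    for (gi in seq_along(groups)) {
      idx <- split[[gi]]$train
      if (!length(idx)) next
      idx <- with_local_seed(derive_seed(order_seed, gi), sample(idx))
      nb <- ceiling(length(idx) / train_cfg$batch_size)
      for (b in seq_len(nb)) {
        sel <- idx[((b - 1) * train_cfg$batch_size + 1):
                     min(b * train_cfg$batch_size, length(idx))]
        st <- unet_train_step(model, opt,
                              groups[[gi]]$x[, , , sel, drop = FALSE],
                              groups[[gi]]$t[, , , sel, drop = FALSE],
                              train_cfg$learning_rate)
        model <- st$model
        opt <- st$opt
        if (!is.finite(st$loss)) {
          abort_dynapet(sprintf(
            "Training diverged at level 1/%g, epoch %d (non-finite loss).",
            1 / lev$factor, ep))
        }
        ep_losses <- c(ep_losses, st$loss)
      }
    }
    vloss <- mean(unlist(lapply(seq_along(groups), function(gi) {
      iv <- split[[gi]]$val
      if (!length(iv)) return(NULL)
      unet_loss(model, groups[[gi]]$x[, , , iv, drop = FALSE],
                groups[[gi]]$t[, , , iv, drop = FALSE])
    })))
    hist[[ep]] <- tibble(epoch = ep, train_loss = mean(ep_losses),
                         val_loss = vloss)
    if (verbose) {
      message(sprintf("  epoch %d: train %.4g val %.4g", ep,
                      mean(ep_losses), vloss))
    }
    if (vloss < best$val - 1e-12) {
      best <- list(val = vloss, model = model, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= train_cfg$patience) break
    }
  }
  list(model = best$model, history = dplyr::bind_rows(hist))
}

# replicate-pad the first two dims of (H, W, C, N) up to a multiple of m
pad_to_mult <- function(x, m) {
  d <- dim(x)
  H2 <- ceiling(d[1] / m) * m
  W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(x)
  ih <- c(seq_len(d[1]), rep(d[1], H2 - d[1]))
  iw <- c(seq_len(d[2]), rep(d[2], W2 - d[2]))
  x[ih, iw, , , drop = FALSE]
}

#' Match a frame to the closest-count training level
#'
#' Chooses the bank level whose reference total counts are closest to the
#' frame's total counts on a log scale; exact ties go to the lower-count
#' level. Frames above the highest reference clamp to the highest-count
#' level. A zero-count frame maps to the lowest-count level with a warning.
#'
#' @param bank A [train_bank()] result.
#' @param total_counts Total expected counts of the frame.
#' @return Integer index into `bank$levels` with the matched `count_level`
#'   as attribute `level`.
#' @export
match_level <- function(bank, total_counts) {
  stopifnot(inherits(bank, "denoiser_bank"))
  refs <- vapply(bank$levels, function(l) l$level$ref_total_counts, 0)
  if (total_counts <= 0) {
    warn("Zero-count frame; using the lowest-count level.")
    i <- which.min(refs)
  } else {
    dist <- abs(log(total_counts) - log(refs))
    i <- order(dist, refs)[1]  # tie -> lower-count level
  }
  structure(i, level = bank$levels[[i]]$level)
}

#' Denoise a single 3D frame with a bank network
#'
#' Applies the selected network along transverse, coronal and sagittal
#' views (3-slice windows, per-slice mean normalization, middle-slice
#' prediction, un-normalization by the input middle-slice mean) and
#' averages the three view volumes. Zero-mean slices pass through
#' unchanged.
#'
#' @param frame 3D array.
#' @param bank A [train_bank()] result.
#' @param level Level index (e.g. from [match_level()]); required unless
#'   `total_counts` is given for automatic matching.
#' @param total_counts Frame total counts for automatic level matching.
#' @return Denoised 3D array.
#' @export
denoise_frame <- function(frame, bank, level = NULL, total_counts = NULL) {
  stopifnot(inherits(bank, "denoiser_bank"))
  if (is.null(level)) {
    if (is.null(total_counts)) {
      abort_dynapet("Give either `level` or `total_counts`.")
    }
    level <- match_level(bank, total_counts)
  }
  model <- bank$levels[[level]]$model
  D <- bank$net_cfg$depth
  if (any(dim(frame) < 2^D)) {
    abort_dynapet("Frame spatial dims are below the network's minimum size.")
  }
  acc <- array(0, dim(frame))
  for (p in view_perms) {
    vp <- aperm(frame, p)
    win <- slice_windows(vp)
    nw <- normalize_windows(win)
    xin <- pad_to_mult(nw$win, 2^D)
    pred <- unet_fwd(model, xin, training = FALSE)$y
    d0 <- dim(win)
    pred <- pred[seq_len(d0[1]), seq_len(d0[2]), 1, , drop = TRUE]
    if (length(dim(pred)) < 3) dim(pred) <- d0[c(1, 2, 4)]
    out <- vp
    for (k in which(nw$usable)) out[, , k] <- pred[, , k] * nw$mid_mean[k]
    acc <- acc + aperm(out, inv_perm(p))
  }
  acc / length(view_perms)
}

#' Denoise a dynamic image frame by frame
#'
#' Each frame is routed to the bank level whose training count statistics
#' most closely match the frame's total expected counts (from the image's
#' calibration record), then denoised with [denoise_frame()].
#'
#' @param image A [dynamic_image()].
#' @param bank A [train_bank()] result.
#' @param level_override Optional level index forcing one network for all
#'   frames.
#' @return A [dynamic_image()]; the per-frame routing is attached as
#'   attribute `levels` (tibble: frame, total_counts, level, factor).
#' @export
denoise_dynamic <- function(image, bank, level_override = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  cnt <- expected_counts(image)
  d <- dim(image$voxels)
  totals <- colSums(matrix(cnt, ncol = d[4]))
  out <- image$voxels
  lv <- integer(d[4])
  for (f in seq_len(d[4])) {
    lev <- if (!is.null(level_override)) level_override
           else as.integer(match_level(bank, totals[f]))
    lv[f] <- lev
    out[, , , f] <- denoise_frame(image$voxels[, , , f], bank, level = lev)
  }
  res <- dynamic_image(out, image$voxel_size_mm, image$schedule,
                       image$calibration)
  attr(res, "levels") <- tibble(
    frame = seq_len(d[4]), total_counts = totals, level = lv,
    factor = vapply(lv, function(i) bank$levels[[i]]$level$factor, 0))
  res
}

#' Classical Gaussian smoothing baseline
#'
#' Isotropic Gaussian smoothing with the stated full width at half maximum;
#' `fwhm_mm = 0` is the identity. Edges use replicate padding, so total
#' activity of interior structures is conserved.
#'
#' @param frame 3D array.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @param voxel_size_mm Voxel size (mm), length 1 or 3.
#' @return Smoothed 3D array.
#' @export
gaussian_denoise <- function(frame, fwhm_mm, voxel_size_mm = c(4, 4, 4)) {
  if (fwhm_mm < 0) abort_dynapet("`fwhm_mm` must be >= 0.")
  if (fwhm_mm == 0) return(frame)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  gauss_filter3(frame, sigma, truncate = 4)
}

#' Serialize / load a denoiser bank
#'
#' Writes one weights file per level plus a JSON manifest (factors,
#' reference counts, configurations, parameter count).
#'
#' @param bank A [train_bank()] result.
#' @param dir Output directory (created if needed).
#' @return `write_bank` returns `dir` invisibly; `read_bank` the bank.
#' @export
write_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    n_levels = length(bank$levels),
    factors = vapply(bank$levels, function(l) l$level$factor, 0),
    ref_total_counts = vapply(bank$levels,
                              function(l) l$level$ref_total_counts, 0),
    net_cfg = unclass(bank$net_cfg),
    train_cfg = unclass(bank$train_cfg),
    n_params = n_params(bank$net_cfg)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(bank$levels)) {
    saveRDS(bank$levels[[i]], file.path(dir, sprintf("level_%02d.rds", i)))
  }
  invisible(dir)
}

#' @rdname write_bank
#' @export
read_bank <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  levels <- lapply(seq_len(manifest$n_levels), function(i) {
    readRDS(file.path(dir, sprintf("level_%02d.rds", i)))
  })
  net_cfg <- do.call(net_config, manifest$net_cfg[
    c("depth", "base_channels", "attention_gates", "residual", "in_slices")])
  train_cfg <- do.call(train_config, manifest$train_cfg[
    c("learning_rate", "batch_size", "epochs", "seed", "val_fraction",
      "patience")])
  structure(list(levels = levels, net_cfg = net_cfg, train_cfg = train_cfg),
            class = "denoiser_bank")
}
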