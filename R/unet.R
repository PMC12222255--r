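# Attention-gated 2D U-Net with residual output, hand-authored:
# forward/backward passes are written against the compiled conv/pool/
# upsample kernels, with batch normalization, parametric ReLU and additive
# attention gates on the skip connections.  Tensors are column-major R
# arrays (H, W, C, B); gradients are exact (finite-difference checked in
# the test suite).

#' Network configuration for the denoiser U-Net
#'
#' @param depth Number of pooling stages (default 3: three max-pool and
#'   three bilinear up-sampling operations).
#' @param base_channels Channels of the first encoder stage; doubled per
#'   stage and capped at `4 * base_channels` (default 16).
#' @param attention_gates Use additive attention gates on the skip
#'   connections (default TRUE).
#' @param residual Add the input middle slice to the network output so the
#'   network learns a correction (default TRUE).
#' @param in_slices Input channels; fixed at 3 consecutive slices.
#' @return A list of class `net_config`.
#' @export
net_config <- function(depth = 3, base_channels = 16, attention_gates = TRUE,
                       residual = TRUE, in_slices = 3) {
  if (depth < 1) abort_dynapet("`depth` must be >= 1.")
  if (in_slices != 3) abort_dynapet("The denoiser takes 3 consecutive slices.")
  ch <- pmin(base_channels * 2^(0:(depth - 1)), 4 * base_channels)
  structure(list(depth = depth, base_channels = base_channels,
                 channels = ch, attention_gates = attention_gates,
                 residual = residual, in_slices = in_slices),
            class = "net_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-5, the full-scale
#'   setting; the desk-scale demo bank uses a larger rate, see the
#'   vignette).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Maximum epochs.
#' @param seed Seed controlling initialization, the train/validation split
#'   and batch shuffling.
#' @param val_fraction Fraction of slices held out for validation
#'   (default 0.1).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 32, epochs = 100,
                         seed = 1, val_fraction = 0.1, patience = 10) {
  if (learning_rate <= 0) abort_dynapet("`learning_rate` must be > 0.")
  if (batch_size < 1) abort_dynapet("`batch_size` must be >= 1.")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = seed, val_fraction = val_fraction,
                 patience = patience),
            class = "train_config")
}

unet_block_names <- function(cfg) {
  c(paste0("enc", seq_len(cfg$depth)), "bott",
    paste0("dec", seq_len(cfg$depth)))
}

# (kh, kw, ci, co) He-initialized kernel
he_kernel <- function(kh, kw, ci, co) {
  array(stats::rnorm(kh * kw * ci * co, sd = sqrt(2 / (kh * kw * ci))),
        c(kh, kw, ci, co))
}

unet_init <- function(cfg, seed = 1) {
  with_local_seed(seed, {
    ch <- cfg$channels
    D <- cfg$depth
    ins <- c(cfg$in_slices, ch[-D])         # encoder block input channels
    P <- list(); S <- list()
    add_block <- function(nm, ci, co) {
      P[[paste0(nm, ".c1.W")]] <<- he_kernel(3, 3, ci, co)
      P[[paste0(nm, ".c1.b")]] <<- numeric(co)
      P[[paste0(nm, ".bn1.g")]] <<- rep(1, co)
      P[[paste0(nm, ".bn1.b")]] <<- numeric(co)
      P[[paste0(nm, ".pr1.a")]] <<- rep(0.25, co)
      P[[paste0(nm, ".c2.W")]] <<- he_kernel(3, 3, co, co)
      P[[paste0(nm, ".c2.b")]] <<- numeric(co)
      P[[paste0(nm, ".bn2.g")]] <<- rep(1, co)
      P[[paste0(nm, ".bn2.b")]] <<- numeric(co)
      P[[paste0(nm, ".pr2.a")]] <<- rep(0.25, co)
      S[[paste0(nm, ".bn1")]] <<- list(mean = numeric(co), var = rep(1, co))
      S[[paste0(nm, ".bn2")]] <<- list(mean = numeric(co), var = rep(1, co))
    }
    for (i in seq_len(D)) add_block(paste0("enc", i), ins[i], ch[i])
    add_block("bott", ch[D], ch[D])
    for (i in seq_len(D)) {
      gch <- if (i == D) ch[D] else ch[i + 1]   # channels arriving from below
      add_block(paste0("dec", i), ch[i] + gch, ch[i])
      if (cfg$attention_gates) {
        cint <- max(ch[i] %/% 2, 4)
        P[[paste0("att", i, ".Wt")]] <- he_kernel(1, 1, ch[i], cint)
        P[[paste0("att", i, ".bt")]] <- numeric(cint)
        P[[paste0("att", i, ".Wg")]] <- he_kernel(1, 1, gch, cint)
        P[[paste0("att", i, ".bg")]] <- numeric(cint)
        P[[paste0("att", i, ".Wp")]] <- he_kernel(1, 1, cint, 1)
        # bias 2 so gates start nearly open: the net begins close to identity
        P[[paste0("att", i, ".bp")]] <- 2
      }
    }
    # zero-initialized output head: the residual net starts as the identity
    P[["out.W"]] <- array(0, c(1, 1, ch[1], 1))
    P[["out.b"]] <- 0
    list(params = P, stats = S, cfg = cfg)
  })
}

#' Number of trainable parameters of a network configuration
#' @param cfg A [net_config()].
#' @return Integer parameter count.
#' @export
n_params <- function(cfg) {
  m <- unet_init(cfg, seed = 1)
  sum(vapply(m$params, length, 0L))
}

# per-channel reductions over (H, W, B) without aperm: fold (H*W) first,
# then collapse the C x B slice summaries
ch_mean <- function(z, hw, C, B) {
  rowMeans(matrix(colMeans(matrix(z, nrow = hw)), C, B))
}

bn_fwd <- function(x, g, b, training, st, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  if (training) {
    mu <- ch_mean(x, hw, C, B)
    va <- ch_mean(x * x, hw, C, B) - mu^2
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va
  } else {
    mu <- st$mean
    va <- st$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x - rep(mu, each = hw)) * rep(invstd, each = hw)
  y <- xhat * rep(g, each = hw) + rep(b, each = hw)
  list(y = y, stats = st,
       cache = list(xhat = xhat, invstd = invstd, g = g, dim = d))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dim
  hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  n <- hw * B
  xhat <- cache$xhat
  dg <- ch_mean(dy * xhat, hw, C, B) * n
  db <- ch_mean(dy, hw, C, B) * n
  dxhat <- dy * rep(cache$g, each = hw)
  # population-statistics backward
  dx <- (dxhat - rep(ch_mean(dxhat, hw, C, B), each = hw) -
           xhat * rep(ch_mean(dxhat * xhat, hw, C, B), each = hw)) *
    rep(cache$invstd, each = hw)
  list(dx = dx, dg = dg, db = db)
}

prelu_fwd <- function(x, a) {
  hw <- dim(x)[1] * dim(x)[2]
  av <- rep(a, each = hw)
  y <- pmax(x, 0) + av * pmin(x, 0)
  dim(y) <- dim(x)
  list(y = y, cache = list(x = x, a = a))
}

prelu_bwd <- function(dy, cache) {
  x <- cache$x
  d <- dim(x)
  hw <- d[1] * d[2]
  av <- rep(cache$a, each = hw)
  dx <- dy * ((x > 0) + av * (x <= 0))
  dim(dx) <- d
  da <- ch_mean(dy * pmin(x, 0), hw, d[3], d[4]) * (hw * d[4])
  list(dx = dx, da = da)
}

block_fwd <- function(P, S, nm, x, training) {
  c1 <- conv2d_fwd_cpp(x, P[[paste0(nm, ".c1.W")]], P[[paste0(nm, ".c1.b")]])
  b1 <- bn_fwd(c1, P[[paste0(nm, ".bn1.g")]], P[[paste0(nm, ".bn1.b")]],
               training, S[[paste0(nm, ".bn1")]])
  p1 <- prelu_fwd(b1$y, P[[paste0(nm, ".pr1.a")]])
  c2 <- conv2d_fwd_cpp(p1$y, P[[paste0(nm, ".c2.W")]], P[[paste0(nm, ".c2.b")]])
  b2 <- bn_fwd(c2, P[[paste0(nm, ".bn2.g")]], P[[paste0(nm, ".bn2.b")]],
               training, S[[paste0(nm, ".bn2")]])
  p2 <- prelu_fwd(b2$y, P[[paste0(nm, ".pr2.a")]])
  S[[paste0(nm, ".bn1")]] <- b1$stats
  S[[paste0(nm, ".bn2")]] <- b2$stats
  list(y = p2$y, stats = S,
       cache = list(x = x, c1 = c1, bn1 = b1$cache, pr1 = p1$cache,
                    p1y = p1$y, bn2 = b2$cache, pr2 = p2$cache))
}

block_bwd <- function(P, G, nm, dy, cache) {
  r2 <- prelu_bwd(dy, cache$pr2)
  G[[paste0(nm, ".pr2.a")]] <- G[[paste0(nm, ".pr2.a")]] %+0% r2$da
  bb2 <- bn_bwd(r2$dx, cache$bn2)
  G[[paste0(nm, ".bn2.g")]] <- G[[paste0(nm, ".bn2.g")]] %+0% bb2$dg
  G[[paste0(nm, ".bn2.b")]] <- G[[paste0(nm, ".bn2.b")]] %+0% bb2$db
  cb2 <- conv2d_bwd_cpp(cache$p1y, P[[paste0(nm, ".c2.W")]], bb2$dx)
  G[[paste0(nm, ".c2.W")]] <- G[[paste0(nm, ".c2.W")]] %+0% cb2$dw
  G[[paste0(nm, ".c2.b")]] <- G[[paste0(nm, ".c2.b")]] %+0% cb2$db
  r1 <- prelu_bwd(cb2$dx, cache$pr1)
  G[[paste0(nm, ".pr1.a")]] <- G[[paste0(nm, ".pr1.a")]] %+0% r1$da
  bb1 <- bn_bwd(r1$dx, cache$bn1)
  G[[paste0(nm, ".bn1.g")]] <- G[[paste0(nm, ".bn1.g")]] %+0% bb1$dg
  G[[paste0(nm, ".bn1.b")]] <- G[[paste0(nm, ".bn1.b")]] %+0% bb1$db
  cb1 <- conv2d_bwd_cpp(cache$x, P[[paste0(nm, ".c1.W")]], bb1$dx)
  G[[paste0(nm, ".c1.W")]] <- G[[paste0(nm, ".c1.W")]] %+0% cb1$dw
  G[[paste0(nm, ".c1.b")]] <- G[[paste0(nm, ".c1.b")]] %+0% cb1$db
  list(dx = cb1$dx, grads = G)
}

`%+0%` <- function(a, b) if (is.null(a)) b else a + b

sigmoid <- function(x) 1 / (1 + exp(-x))

att_fwd <- function(P, nm, s, g) {
  tx <- conv2d_fwd_cpp(s, P[[paste0(nm, ".Wt")]], P[[paste0(nm, ".bt")]])
  pg <- conv2d_fwd_cpp(g, P[[paste0(nm, ".Wg")]], P[[paste0(nm, ".bg")]])
  q0 <- tx + pg
  q <- pmax(q0, 0)
  psi <- conv2d_fwd_cpp(q, P[[paste0(nm, ".Wp")]], P[[paste0(nm, ".bp")]])
  a <- sigmoid(psi)
  C <- dim(s)[3]
  aB <- a[, , rep(1L, C), , drop = FALSE]
  list(y = s * aB,
       cache = list(s = s, g = g, q0 = q0, q = q, a = a))
}

att_bwd <- function(P, G, nm, dy, cache) {
  s <- cache$s
  C <- dim(s)[3]
  a <- cache$a
  aB <- a[, , rep(1L, C), , drop = FALSE]
  ds_direct <- dy * aB
  # da summed over channels -> (H, W, 1, B)
  prod <- dy * s
  da <- array(0, dim(a))
  for (c in seq_len(C)) da <- da + prod[, , c, , drop = FALSE]
  dpsi <- da * a * (1 - a)
  cbp <- conv2d_bwd_cpp(cache$q, P[[paste0(nm, ".Wp")]], dpsi)
  G[[paste0(nm, ".Wp")]] <- G[[paste0(nm, ".Wp")]] %+0% cbp$dw
  G[[paste0(nm, ".bp")]] <- G[[paste0(nm, ".bp")]] %+0% cbp$db
  dq <- cbp$dx
  dq[cache$q0 <= 0] <- 0
  cbt <- conv2d_bwd_cpp(s, P[[paste0(nm, ".Wt")]], dq)
  G[[paste0(nm, ".Wt")]] <- G[[paste0(nm, ".Wt")]] %+0% cbt$dw
  G[[paste0(nm, ".bt")]] <- G[[paste0(nm, ".bt")]] %+0% cbt$db
  cbg <- conv2d_bwd_cpp(cache$g, P[[paste0(nm, ".Wg")]], dq)
  G[[paste0(nm, ".Wg")]] <- G[[paste0(nm, ".Wg")]] %+0% cbg$dw
  G[[paste0(nm, ".bg")]] <- G[[paste0(nm, ".bg")]] %+0% cbg$db
  list(ds = ds_direct + cbt$dx, dg = cbg$dx, grads = G)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_fwd <- function(model, x, training = FALSE) {
  P <- model$params; S <- model$stats; cfg <- model$cfg
  D <- cfg$depth
  cache <- list(x = x)
  enc <- vector("list", D)
  h <- x
  for (i in seq_len(D)) {
    r <- block_fwd(P, S, paste0("enc", i), h, training)
    S <- r$stats
    enc[[i]] <- r$y
    cache[[paste0("enc", i)]] <- r$cache
    pr <- maxpool2_fwd_cpp(r$y)
    cache[[paste0("pool", i)]] <- list(argmax = pr$argmax,
                                       dim = as.integer(dim(r$y)))
    h <- pr$y
  }
  r <- block_fwd(P, S, "bott", h, training)
  S <- r$stats
  cache$bott <- r$cache
  g <- r$y
  for (i in rev(seq_len(D))) {
    gu <- upsample2_fwd_cpp(g)
    cache[[paste0("updim", i)]] <- as.integer(dim(g))
    if (cfg$attention_gates) {
      ar <- att_fwd(P, paste0("att", i), enc[[i]], gu)
      sg <- ar$y
      cache[[paste0("att", i)]] <- ar$cache
    } else sg <- enc[[i]]
    cc <- concat_ch(sg, gu)
    cache[[paste0("nsplit", i)]] <- dim(sg)[3]
    r <- block_fwd(P, S, paste0("dec", i), cc, training)
    S <- r$stats
    cache[[paste0("dec", i)]] <- r$cache
    g <- r$y
  }
  out <- conv2d_fwd_cpp(g, P$out.W, P$out.b)
  cache$head_in <- g
  y <- if (cfg$residual) out + x[, , 2, , drop = FALSE] else out
  list(y = y, stats = S, cache = cache)
}

unet_bwd <- function(model, cache, dy) {
  P <- model$params; cfg <- model$cfg
  D <- cfg$depth
  G <- list()
  cbo <- conv2d_bwd_cpp(cache$head_in, P$out.W, dy)
  G[["out.W"]] <- cbo$dw
  G[["out.b"]] <- cbo$db
  dg <- cbo$dx
  denc <- vector("list", D)
  for (i in seq_len(D)) {   # reverse of the decoder loop (which ran D..1)
    r <- block_bwd(P, G, paste0("dec", i), dg, cache[[paste0("dec", i)]])
    G <- r$grads
    nS <- cache[[paste0("nsplit", i)]]
    dcc <- r$dx
    dsg <- dcc[, , seq_len(nS), , drop = FALSE]
    dgu <- dcc[, , nS + seq_len(dim(dcc)[3] - nS), , drop = FALSE]
    if (cfg$attention_gates) {
      ar <- att_bwd(P, G, paste0("att", i), dsg, cache[[paste0("att", i)]])
      G <- ar$grads
      denc[[i]] <- ar$ds
      dgu <- dgu + ar$dg
    } else {
      denc[[i]] <- dsg
    }
    dg <- upsample2_bwd_cpp(dgu, cache[[paste0("updim", i)]])
  }
  r <- block_bwd(P, G, "bott", dg, cache$bott)
  G <- r$grads
  dp <- r$dx
  for (i in rev(seq_len(D))) {
    de <- maxpool2_bwd_cpp(dp, cache[[paste0("pool", i)]]$argmax,
                           cache[[paste0("pool", i)]]$dim) + denc[[i]]
    r <- block_bwd(P, G, paste0("enc", i), de, cache[[paste0("enc", i)]])
    G <- r$grads
    dp <- r$dx
  }
  G
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one optimization step on a batch; returns loss and updated model/opt
unet_train_step <- function(model, opt, xb, tb, lr) {
  fw <- unet_fwd(model, xb, training = TRUE)
  model$stats <- fw$stats
  resid <- fw$y - tb
  loss <- mean(resid^2)
  dy <- 2 * resid / length(resid)
  G <- unet_bwd(model, fw$cache, dy)
  st <- adam_step(model$params, G, opt, lr)
  model$params <- st$params
  list(model = model, opt = st$state, loss = loss)
}

unet_loss <- function(model, x, t) {
  fw <- unet_fwd(model, x, training = FALSE)
  mean((fw$y - t)^2)
}
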