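# Internal neural-network machinery for the velocity decoder.
#
# The network is small enough that plain BLAS-backed matrix ops are fast on
# one CPU, so forward, backward and the Adam optimizer are implemented
# directly. Layout of a parameter set (see init_decoder for the public
# constructor):
#   Wt (3 x n_time_features), bt       -- temporal feature layer, weights
#                                         shared across channels
#   bn0, W1/b1/bn1, W2/b2/bn2, W3/b3/bn3
#                                      -- hidden fully connected stack,
#                                         ReLU -> batchnorm -> dropout
#   W4                                 -- final linear layer, no bias
#   bnf                                -- final batchnorm: variance-only
#                                         (never subtracts a mean) and with
#                                         no learnable bias
# Batch matrices are n x p (rows = samples).

.bn_new <- function(p, affine = TRUE) {
  list(gamma = rep(1, p), beta = if (affine) rep(0, p) else NULL,
       rmean = rep(0, p), rvar = rep(1, p))
}

# standard batchnorm; training uses batch statistics and updates running ones
.bn_forward <- function(bn, H, training, eps, momentum) {
  n <- nrow(H)
  if (training && n > 1) {
    mu <- colMeans(H)
    xc <- H - rep(mu, each = n)
    v <- colMeans(xc * xc)
    s <- sqrt(v + eps)
    xhat <- xc / rep(s, each = n)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
    cache <- list(xhat = xhat, s = s)
  } else {
    s <- sqrt(bn$rvar + eps)
    xhat <- (H - rep(bn$rmean, each = n)) / rep(s, each = n)
    cache <- NULL
  }
  out <- xhat * rep(bn$gamma, each = n)
  if (!is.null(bn$beta)) out <- out + rep(bn$beta, each = n)
  list(out = out, bn = bn, cache = cache)
}

.bn_backward <- function(bn, cache, dOut) {
  n <- nrow(dOut)
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- if (!is.null(bn$beta)) colSums(dOut) else NULL
  g_s <- bn$gamma / cache$s
  m1 <- colMeans(dOut)
  m2 <- colMeans(dOut * xhat)
  dH <- (dOut - rep(m1, each = n) - xhat * rep(m2, each = n)) *
    rep(g_s, each = n)
  list(dH = dH, dgamma = dgamma, dbeta = dbeta)
}

# variance-only batchnorm: y = gamma * x / sqrt(var + eps). The variance is
# still computed about the batch mean, but no mean is ever subtracted and no
# bias is learned, in training or inference, so the layer cannot hide a
# nonzero output mean.
.bnv_forward <- function(bn, H, training, eps, momentum) {
  n <- nrow(H)
  if (training && n > 1) {
    mu <- colMeans(H)
    xc <- H - rep(mu, each = n)
    v <- colMeans(xc * xc)
    s <- sqrt(v + eps)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
    cache <- list(H = H, mu = mu, s = s)
  } else {
    s <- sqrt(bn$rvar + eps)
    cache <- NULL
  }
  out <- H / rep(s, each = n) * rep(bn$gamma, each = n)
  list(out = out, bn = bn, cache = cache, s = s)
}

.bnv_backward <- function(bn, cache, dOut) {
  n <- nrow(dOut)
  H <- cache$H; s <- cache$s; mu <- cache$mu
  dgamma <- colSums(dOut * H / rep(s, each = n))
  # y_i = g x_i / s with s depending on the whole batch column
  dot <- colSums(dOut * H)               # sum_i dOut_i x_i, per column
  xc <- H - rep(mu, each = n)
  dH <- rep(bn$gamma / s, each = n) *
    (dOut - xc * rep(dot / (n * s^2), each = n))
  list(dH = dH, dgamma = dgamma)
}

# forward pass; windows is E_N x 3 x n (or a single E_N x 3 matrix).
# Returns the n x dof raw output, updated running stats (training), and a
# cache for backprop when requested.
.nn_forward <- function(params, windows, training = FALSE,
                        want_cache = FALSE) {
  cfg <- params$config
  eps <- cfg$bn_eps; mom <- cfg$bn_momentum
  if (is.matrix(windows)) windows <- array(windows, c(dim(windows), 1L))
  en <- dim(windows)[1]; n <- dim(windows)[3]
  if (en != cfg$n_channels || dim(windows)[2] != 3L) {
    stop(sprintf("window must be %d x 3", cfg$n_channels), call. = FALSE)
  }
  M <- matrix(aperm(windows, c(2L, 1L, 3L)), nrow = 3L)   # 3 x (en*n)
  Fmat <- crossprod(params$Wt, M) + params$bt             # nf x (en*n)
  nf <- cfg$n_time_features
  H <- t(matrix(Fmat, nf * en, n))                        # n x (nf*en)
  cache <- if (want_cache) list(M = M, n = n, en = en) else NULL
  relu_caches <- vector("list", 4L)
  bn_caches <- vector("list", 4L)
  drop_masks <- vector("list", 4L)
  lin_inputs <- vector("list", 4L)

  act <- function(H, i) {
    mask_neg <- H > 0
    H <- H * mask_neg
    if (want_cache) relu_caches[[i]] <<- mask_neg
    bnp <- params[[paste0("bn", i - 1L)]]
    r <- .bn_forward(bnp, H, training, eps, mom)
    if (training) params[[paste0("bn", i - 1L)]] <<- r$bn
    if (want_cache) bn_caches[[i]] <<- r$cache
    H <- r$out
    if (training && cfg$dropout > 0) {
      keep <- 1 - cfg$dropout
      m <- matrix(stats::runif(length(H)) < keep, nrow(H)) / keep
      H <- H * m
      if (want_cache) drop_masks[[i]] <<- m
    }
    H
  }

  H <- act(H, 1L)
  for (l in 1:3) {
    if (want_cache) lin_inputs[[l]] <- H
    H <- H %*% params[[paste0("W", l)]] +
      rep(params[[paste0("b", l)]], each = nrow(H))
    H <- act(H, l + 1L)
  }
  if (want_cache) lin_inputs[[4L]] <- H
  H <- H %*% params$W4                                    # no bias
  rf <- .bnv_forward(params$bnf, H, training, eps, mom)
  if (training) params$bnf <- rf$bn
  out <- rf$out
  if (want_cache) {
    cache$relu <- relu_caches; cache$bn <- bn_caches
    cache$drop <- drop_masks; cache$lin <- lin_inputs
    cache$bnf <- rf$cache
  }
  list(out = out, params = params, cache = cache)
}

# backward pass; dOut is n x dof. Returns gradients named like the params.
.nn_backward <- function(params, cache, dOut) {
  cfg <- params$config
  grads <- list()
  bb <- .bnv_backward(params$bnf, cache$bnf, dOut)
  grads$bnf_gamma <- bb$dgamma
  dH <- bb$dH
  grads$W4 <- crossprod(cache$lin[[4L]], dH)
  dH <- tcrossprod(dH, params$W4)

  back_act <- function(dH, i) {
    if (!is.null(cache$drop[[i]])) dH <- dH * cache$drop[[i]]
    bnp <- params[[paste0("bn", i - 1L)]]
    r <- .bn_backward(bnp, cache$bn[[i]], dH)
    grads[[paste0("bn", i - 1L, "_gamma")]] <<- r$dgamma
    grads[[paste0("bn", i - 1L, "_beta")]] <<- r$dbeta
    r$dH * cache$relu[[i]]
  }

  for (l in 3:1) {
    dH <- back_act(dH, l + 1L)
    grads[[paste0("W", l)]] <- crossprod(cache$lin[[l]], dH)
    grads[[paste0("b", l)]] <- colSums(dH)
    dH <- tcrossprod(dH, params[[paste0("W", l)]])
  }
  dH <- back_act(dH, 1L)
  # temporal layer: reshape n x (nf*en) back to nf x (en*n)
  nf <- cfg$n_time_features
  GF <- matrix(t(dH), nrow = nf)
  grads$Wt <- tcrossprod(cache$M, GF)   # (3 x nf)
  grads$bt <- rowSums(GF)
  grads
}

# flatten trainable params to a named list for the optimizer
.nn_param_refs <- function(params) {
  refs <- list(Wt = "Wt", bt = "bt", W4 = "W4")
  for (l in 1:3) {
    refs[[paste0("W", l)]] <- paste0("W", l)
    refs[[paste0("b", l)]] <- paste0("b", l)
  }
  refs
}

.nn_get_flat <- function(params) {
  out <- list(Wt = params$Wt, bt = params$bt,
              W1 = params$W1, b1 = params$b1,
              W2 = params$W2, b2 = params$b2,
              W3 = params$W3, b3 = params$b3,
              W4 = params$W4,
              bnf_gamma = params$bnf$gamma)
  for (i in 0:3) {
    out[[paste0("bn", i, "_gamma")]] <- params[[paste0("bn", i)]]$gamma
    out[[paste0("bn", i, "_beta")]] <- params[[paste0("bn", i)]]$beta
  }
  out
}

.nn_set_flat <- function(params, flat) {
  for (nm in c("Wt", "bt", "W1", "b1", "W2", "b2", "W3", "b3", "W4")) {
    params[[nm]] <- flat[[nm]]
  }
  params$bnf$gamma <- flat$bnf_gamma
  for (i in 0:3) {
    params[[paste0("bn", i)]]$gamma <- flat[[paste0("bn", i, "_gamma")]]
    params[[paste0("bn", i)]]$beta <- flat[[paste0("bn", i, "_beta")]]
  }
  params
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

# one Adam step (coupled weight decay, as in torch.optim.Adam)
.adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# shared minibatch training loop; returns updated params and the loss trace
.nn_fit <- function(params, windows, targets, n_iter, lr, batch_size,
                    weight_decay = 0, shuffle = TRUE) {
  n <- dim(windows)[3]
  flat <- .nn_get_flat(params)
  state <- .adam_init(flat)
  losses <- numeric(0)
  it <- 0L
  while (it < n_iter) {
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    for (start in seq(1L, n, by = batch_size)) {
      if (it >= n_iter) break
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next   # batchnorm needs at least 2 samples
      wb <- windows[, , idx, drop = FALSE]
      tb <- targets[idx, , drop = FALSE]
      fw <- .nn_forward(params, wb, training = TRUE, want_cache = TRUE)
      params <- fw$params
      err <- fw$out - tb
      loss <- mean(err * err)
      dOut <- 2 * err / length(err)
      grads <- .nn_backward(params, fw$cache, dOut)
      flat <- .nn_get_flat(params)
      st <- .adam_step(flat, grads, state, lr = lr,
                       weight_decay = weight_decay)
      params <- .nn_set_flat(params, st$flat)
      state <- st$state
      it <- it + 1L
      losses[it] <- loss
    }
  }
  list(params = params, losses = losses)
}

# inference-mode outputs in manageable batches
.nn_predict <- function(params, windows, batch = 1024L) {
  if (is.matrix(windows)) windows <- array(windows, c(dim(windows), 1L))
  n <- dim(windows)[3]
  out <- matrix(0, n, params$config$dof)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx, ] <- .nn_forward(params, windows[, , idx, drop = FALSE],
                              training = FALSE)$out
  }
  out
}
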