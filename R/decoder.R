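#' Decoder architecture configuration
#'
#' The velocity decoder is a shallow temporally convolved feed-forward
#' network. A temporal feature layer with weights shared across channels
#' contracts the three most recent 50-ms SBP bins into `n_time_features`
#' learned features per channel; the flattened feature vector then passes
#' through four fully connected layers, ReLU after every linear map except
#' the last, with batch normalization and 50% dropout regularizing each
#' intermediate output. To keep the decoded velocities mean-free by
#' construction, the final linear layer carries no bias and the final
#' batchnorm learns no bias and applies a variance correction only --
#' never a mean correction, in training or inference.
#'
#' @param n_channels number of SBP channels (E_N).
#' @param dof decoded degrees of freedom; the last hidden width must equal
#'   this.
#' @param n_time_features learned temporal features per channel (default
#'   16).
#' @param hidden_widths widths of the four fully connected layers; the
#'   default `c(256, 256, 256, dof)` fits comfortably on one CPU.
#' @param dropout dropout rate on intermediate outputs (default 0.5).
#' @param speed_constant global output speed scale (ROM-units/s per
#'   normalized unit, default 1).
#' @return object of class `decoder_config`.
#' @export
decoder_config <- function(n_channels, dof,
                           n_time_features = 16L,
                           hidden_widths = c(256L, 256L, 256L, dof),
                           dropout = 0.5,
                           speed_constant = 1) {
  if (length(hidden_widths) != 4L) {
    stop("`hidden_widths` must have exactly 4 entries", call. = FALSE)
  }
  if (hidden_widths[4L] != dof) {
    stop("the last hidden width must equal `dof`", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels),
    dof = as.integer(dof),
    n_time_bins = 3L,
    n_time_features = as.integer(n_time_features),
    hidden_widths = as.integer(hidden_widths),
    dropout = dropout,
    speed_constant = speed_constant,
    bn_eps = 1e-5,
    bn_momentum = 0.1
  ), class = "decoder_config")
}

#' Initialize decoder parameters
#'
#' Weights are drawn with Kaiming (He) initialization: each linear map's
#' entries are Gaussian with standard deviation `sqrt(2 / fan_in)`, the
#' appropriate scale for ReLU stacks. Biases start at zero, batchnorm
#' scales at one. Output normalization statistics are unset (identity)
#' until training.
#'
#' @param config a [decoder_config()].
#' @param seed integer seed; initialization is deterministic per seed.
#' @return object of class `finger_decoder`.
#' @export
init_decoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "decoder_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  nf <- config$n_time_features
  en <- config$n_channels
  hw <- config$hidden_widths
  kaiming <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
           fan_in, fan_out)
  }
  p0 <- nf * en
  params <- list(
    config = config,
    Wt = kaiming(3L, nf), bt = rep(0, nf),
    bn0 = .bn_new(p0),
    W1 = kaiming(p0, hw[1]), b1 = rep(0, hw[1]), bn1 = .bn_new(hw[1]),
    W2 = kaiming(hw[1], hw[2]), b2 = rep(0, hw[2]), bn2 = .bn_new(hw[2]),
    W3 = kaiming(hw[2], hw[3]), b3 = rep(0, hw[3]), bn3 = .bn_new(hw[3]),
    W4 = kaiming(hw[3], hw[4]),
    bnf = .bn_new(hw[4], affine = FALSE),
    out_mean = NULL, out_sd = NULL,
    gains = rep(1, config$dof),
    version = 0L
  )
  class(params) <- "finger_decoder"
  params
}

#' @export
print.finger_decoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<finger_decoder v%d> %d ch x 3 bins -> %d features -> %s -> %d DOF\n",
    x$version, cfg$n_channels, cfg$n_time_features,
    paste(cfg$hidden_widths, collapse = "-"), cfg$dof))
  cat(if (is.null(x$out_mean)) "  untrained (normalization unset)\n"
      else sprintf("  gains: %s\n", paste(signif(x$gains, 3),
                                          collapse = ", ")))
  invisible(x)
}

#' Decoder forward pass
#'
#' Maps one or more SBP windows to raw decoded velocities (before output
#' normalization and gain). In inference mode dropout is disabled and
#' batchnorm uses running statistics, so the output is a pure function of
#' the parameters and the input; the final batchnorm applies variance
#' scaling only in either mode.
#'
#' @param params a [finger_decoder][init_decoder].
#' @param window `n_channels x 3` matrix, or an `n_channels x 3 x n`
#'   array of windows.
#' @param mode `"inference"` (default) or `"train"` (batch statistics,
#'   dropout active; draws from R's RNG stream).
#' @return `n x dof` matrix of raw velocities (a vector for one window).
#' @export
decoder_forward <- function(params, window, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "finger_decoder"))
  single <- is.matrix(window)
  out <- .nn_forward(params, window, training = (mode == "train"))$out
  if (single) drop(out) else out
}

#' Output normalization and gain
#'
#' Converts raw network output to a physical velocity command:
#' `v = gains * (raw - out_mean) / out_sd * speed_constant`. The mean and
#' standard deviation are empirical statistics of the network's output on
#' its training set (recorded by [train_supervised()]); the gain is the
#' per-DOF scale applied on top (auto-calibrated to the training label
#' scale by default, adjustable with [set_gains()]). No smoothing is
#' applied.
#'
#' @param raw_v raw output (vector or `n x dof` matrix).
#' @param params a trained [finger_decoder][init_decoder].
#' @return velocity in ROM-units/s, same shape as `raw_v`.
#' @export
apply_normalization_and_gain <- function(raw_v, params) {
  stopifnot(inherits(params, "finger_decoder"))
  if (is.null(params$out_mean) || is.null(params$out_sd)) {
    stop("decoder normalization statistics are unset; train it first",
         call. = FALSE)
  }
  single <- !is.matrix(raw_v)
  v <- if (single) matrix(raw_v, 1) else raw_v
  n <- nrow(v)
  v <- (v - rep(params$out_mean, each = n)) / rep(params$out_sd, each = n)
  v <- v * rep(params$gains * params$config$speed_constant, each = n)
  if (single) drop(v) else v
}

#' @rdname apply_normalization_and_gain
#' @param window `n_channels x 3` SBP window (or array of windows).
#' @export
decode_velocity <- function(params, window) {
  apply_normalization_and_gain(decoder_forward(params, window), params)
}

#' @rdname apply_normalization_and_gain
#' @param gains new per-DOF gain vector.
#' @export
set_gains <- function(params, gains) {
  stopifnot(inherits(params, "finger_decoder"))
  params$gains <- rep_len(as.numeric(gains), params$config$dof)
  params$gains_user <- TRUE
  params
}

#' Assemble a training set of windows and velocity labels
#'
#' @param windows `n_channels x 3 x n` array (see [make_windows()]).
#' @param targets `n x dof` matrix of velocity labels (ROM-units/s).
#' @param provenance `"open_loop"` or `"refit_relabel"`, recycled.
#' @return object of class `training_set`.
#' @export
training_set <- function(windows, targets,
                         provenance = "open_loop") {
  targets <- as.matrix(targets)
  if (dim(windows)[3] != nrow(targets)) {
    stop("`windows` and `targets` must have the same number of samples",
         call. = FALSE)
  }
  if (anyNA(targets)) stop("`targets` must not contain NA", call. = FALSE)
  structure(list(windows = windows, targets = targets,
                 provenance = rep_len(provenance, nrow(targets))),
            class = "training_set")
}

#' Build an open-loop training set from a cued block
#'
#' Runs the synthetic population over the block's cued velocities and
#' pairs the resulting 3-bin SBP windows with the cued instantaneous
#' velocities as labels.
#'
#' @param model an [sbp_population][make_population].
#' @param block output of [open_loop_block()].
#' @param seed seed for the emission noise.
#' @return a [training_set()].
#' @export
build_open_loop_training <- function(model, block, seed = 1L) {
  set.seed(as.integer(seed))
  sbp <- emit_sbp_series(model, block$velocities)
  training_set(make_windows(sbp), block$velocities, "open_loop")
}

# per-DOF label standardization; near-constant labels keep scale 1
.label_stats <- function(targets) {
  mu <- colMeans(targets)
  sd <- apply(targets, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

#' Supervised decoder training
#'
#' Minimizes the mean-squared error between the network output and the
#' (per-DOF standardized) velocity labels with minibatch Adam. After
#' fitting, the empirical mean and standard deviation of the network's
#' inference-mode output on the training set are stored as the output
#' normalization statistics, and -- unless gains were set explicitly with
#' [set_gains()] -- the per-DOF gain is calibrated to the training-label
#' standard deviation so that decoded velocities come out on the physical
#' ROM-units/s scale.
#'
#' @param params decoder parameters (from [init_decoder()] or a previous
#'   round of training).
#' @param tset a [training_set()].
#' @param epochs passes over the data (default 60).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size minibatch size (default 64).
#' @param seed seed controlling shuffling and dropout; training is
#'   deterministic per seed.
#' @param standardize_labels standardize labels per DOF before the MSE
#'   (default `TRUE`).
#' @return updated `finger_decoder` (version incremented); the per-batch
#'   loss trace is attached as attribute `"losses"`.
#' @export
train_supervised <- function(params, tset, epochs = 60, learning_rate = 1e-3,
                             batch_size = 64, seed = 1L,
                             standardize_labels = TRUE) {
  stopifnot(inherits(params, "finger_decoder"),
            inherits(tset, "training_set"))
  n <- nrow(tset$targets)
  if (n == 0) stop("empty training set", call. = FALSE)
  set.seed(as.integer(seed))
  targets <- tset$targets
  ls <- .label_stats(targets)
  if (standardize_labels) {
    targets <- (targets - rep(ls$mean, each = n)) / rep(ls$sd, each = n)
  }
  n_iter <- max(1L, epochs * ceiling(n / batch_size))
  fit <- .nn_fit(params, tset$windows, targets, n_iter = n_iter,
                 lr = learning_rate, batch_size = batch_size)
  params <- .finalize_training(fit$params, tset$windows, ls)
  attr(params, "losses") <- fit$losses
  params
}

.finalize_training <- function(params, windows, label_stats) {
  out <- .nn_predict(params, windows)
  params$out_mean <- colMeans(out)
  sdv <- apply(out, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  params$out_sd <- sdv
  if (!isTRUE(params$gains_user)) params$gains <- label_stats$sd
  params$version <- params$version + 1L
  params
}

#' ReFIT intention relabeling
#'
#' Re-labels a closed-loop session under the assumption that the user
#' always intended to move toward the target: per bin and per DOF the
#' label keeps the decoded speed but takes the sign of
#' `target - position`, i.e. the decoded velocity is kept when it pointed
#' toward the target and its sign is inverted when it pointed away.
#' Magnitudes are never altered. Bins where a DOF sits inside its target
#' are labeled zero velocity for that DOF (the user was trying to hold
#' still); set `zero_inside_target = FALSE` to disable.
#'
#' `mode = "vector"` instead treats the decoded velocity as one
#' dof-dimensional vector and relabels it as its magnitude along the unit
#' target-direction vector.
#'
#' @param records trial records from [run_closed_loop_session()] (they
#'   must carry per-bin SBP, decoded velocities and positions).
#' @param zero_inside_target label in-target bins as zero (default TRUE).
#' @param mode `"per_dof"` (default) or `"vector"`.
#' @return a [training_set()] with provenance `"refit_relabel"`.
#' @export
refit_relabel <- function(records, zero_inside_target = TRUE,
                          mode = c("per_dof", "vector")) {
  mode <- match.arg(mode)
  stopifnot(length(records) >= 1)
  win_list <- list(); lab_list <- list()
  for (rec in records) {
    if (is.null(rec$decoded) || is.null(rec$sbp)) {
      stop("records must contain per-bin decoded velocities and SBP",
           call. = FALSE)
    }
    k <- rec$n_bins
    dof <- ncol(rec$decoded)
    pos <- rec$positions[seq_len(k), , drop = FALSE]  # position before bin
    err <- rep(rec$centers, each = k) - pos
    inside <- abs(err) <= rec$width / 2
    dirn <- sign(err)
    labels <- if (mode == "per_dof") {
      lab <- abs(rec$decoded) * dirn
      zero <- rec$decoded == 0
      lab[zero] <- 0
      lab
    } else {
      nrm_e <- sqrt(rowSums((err * !inside)^2))
      unit <- (err * !inside) / ifelse(nrm_e > 0, nrm_e, 1)
      mag <- sqrt(rowSums(rec$decoded^2))
      unit * mag
    }
    if (zero_inside_target) labels[inside] <- 0
    win_list[[length(win_list) + 1L]] <- make_windows(rec$sbp)
    lab_list[[length(lab_list) + 1L]] <- labels
  }
  wins <- do.call(function(...) {
    arrs <- list(...)
    en <- dim(arrs[[1]])[1]
    ntot <- sum(vapply(arrs, function(a) dim(a)[3], 0L))
    out <- array(0, c(en, 3L, ntot))
    at <- 0L
    for (a in arrs) {
      n <- dim(a)[3]
      out[, , at + seq_len(n)] <- a
      at <- at + n
    }
    out
  }, win_list)
  training_set(wins, do.call(rbind, lab_list), "refit_relabel")
}

#' ReFIT parameter update
#'
#' Starting from the parameters used during the online session, applies
#' 500 additional Adam iterations (learning rate 1e-4, weight decay 1e-2)
#' of MSE training on the relabeled set, then refreshes the output
#' normalization statistics.
#'
#' @param params the decoder used online.
#' @param relabeled a [training_set()] from [refit_relabel()].
#' @param seed seed for shuffling/dropout.
#' @param iterations Adam steps (default 500).
#' @param learning_rate,weight_decay update hyperparameters (defaults
#'   1e-4 and 1e-2).
#' @param batch_size minibatch size (default 64).
#' @param standardize_labels standardize labels per DOF as in
#'   [train_supervised()] (default TRUE).
#' @return updated `finger_decoder` (version incremented).
#' @export
refit_update <- function(params, relabeled, seed = 1L, iterations = 500L,
                         learning_rate = 1e-4, weight_decay = 1e-2,
                         batch_size = 64, standardize_labels = TRUE) {
  stopifnot(inherits(params, "finger_decoder"),
            inherits(relabeled, "training_set"))
  if (is.null(params$out_mean)) {
    stop("`params` must come from a previously trained decoder",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(relabeled$targets)
  targets <- relabeled$targets
  ls <- .label_stats(targets)
  if (standardize_labels) {
    targets <- (targets - rep(ls$mean, each = n)) / rep(ls$sd, each = n)
  }
  fit <- .nn_fit(params, relabeled$windows, targets, n_iter = iterations,
                 lr = learning_rate, batch_size = batch_size,
                 weight_decay = weight_decay)
  params <- .finalize_training(fit$params, relabeled$windows, ls)
  attr(params, "losses") <- fit$losses
  params
}
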