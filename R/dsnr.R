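#' Directional signal-to-noise ratio of decoded velocities
#'
#' Each intended direction `v` is a unit vector; the decoded/predicted
#' velocity `v_hat` decomposes into a signal component along `v` and a
#' noise component orthogonal to it. Per bin, the signed signal magnitude
#' is the row-wise dot product `||v_s|| = sum(v_hat * v)`; the angle
#' `theta = acos(||v_s|| / ||v_hat||)` gives the noise magnitude
#' `||v_n|| = sin(theta) * ||v_hat||`; and
#' `dSNR = mean(||v_s||) / sqrt(var(||v_n||) + mean(||v_n||)^2)`, the
#' variance being the population (biased) variance, so the denominator is
#' the root-mean-square orthogonal component.
#'
#' Rows whose intended vector has zero norm (no commanded movement) are
#' excluded. If every retained bin is noiseless the ratio is infinite and
#' `Inf` is returned; if no rows remain the value is `NA`.
#'
#' @param v_hat `n x d` matrix of decoded/predicted velocities.
#' @param v `n x d` matrix of unit-norm intended directions.
#' @return the dSNR (a nonnegative number, `Inf`, or `NA`).
#' @export
dsnr_core <- function(v_hat, v) {
  v_hat <- as.matrix(v_hat); v <- as.matrix(v)
  if (!all(dim(v_hat) == dim(v))) {
    stop("`v_hat` and `v` must have matching dimensions", call. = FALSE)
  }
  keep <- rowSums(v * v) > 1e-12
  if (!any(keep)) return(NA_real_)
  v_hat <- v_hat[keep, , drop = FALSE]
  v <- v[keep, , drop = FALSE]
  s <- rowSums(v_hat * v)
  nrm <- sqrt(rowSums(v_hat^2))
  ratio <- ifelse(nrm > 0, pmin(pmax(s / nrm, -1), 1), 0)
  theta <- acos(ratio)
  noise <- sin(theta) * nrm
  noise_power <- mean((noise - mean(noise))^2) + mean(noise)^2
  if (noise_power <= 0) return(Inf)
  mean(s) / sqrt(noise_power)
}

#' Build a synthetic dSNR dataset from a tuning model
#'
#' Emulates Go-period data: each bin's intended direction is a unit
#' "target corner" vector (equal-magnitude components of random sign on
#' `n_active` randomly chosen DOF, e.g. `(0.707, 0.707)` in 2D), the
#' commanded velocity is that direction times `speed`, and the population
#' emits one SBP bin per intent.
#'
#' @param model an [sbp_population][make_population].
#' @param n_bins number of bins.
#' @param n_active number of simultaneously moving DOF (default
#'   `min(2, dof)`).
#' @param speed commanded speed in ROM-units/s (default 1).
#' @param motor_noise_sd Gaussian noise added to the executed velocity
#'   (not to the intent labels), emulating behavioral variability shared
#'   across all channels. Unlike per-channel noise it cannot be averaged
#'   away by adding channels, so it imposes a ceiling on the dSNR curve
#'   (default 0: the ideal case).
#' @param seed integer seed.
#' @return list of class `dsnr_dataset` with `X` (`n_bins x n_channels`)
#'   and `V` (`n_bins x dof`, unit rows).
#' @export
make_dsnr_dataset <- function(model, n_bins = 5000, n_active = NULL,
                              speed = 1, motor_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "sbp_population"))
  d <- model$dof
  if (is.null(n_active)) n_active <- min(2L, d)
  stopifnot(n_active >= 1, n_active <= d)
  set.seed(as.integer(seed))
  V <- matrix(0, n_bins, d)
  for (i in seq_len(n_bins)) {
    ax <- sample.int(d, n_active)
    V[i, ax] <- sample(c(-1, 1), n_active, replace = TRUE) / sqrt(n_active)
  }
  Vexec <- V * speed
  if (motor_noise_sd > 0) {
    Vexec <- Vexec + matrix(stats::rnorm(n_bins * d, sd = motor_noise_sd),
                            n_bins, d)
  }
  X <- emit_sbp_series(model, Vexec)
  structure(list(X = X, V = V), class = "dsnr_dataset")
}

#' Cross-validated dSNR of a neural dataset
#'
#' The empirical dSNR pipeline: the bins are divided into `n_folds`
#' contiguous folds; for each fold, PCA is fitted on the training folds
#' only and reduces the SBP to `pca_dims` principal-component scores, a
#' linear regression maps the reduced training data to the intended
#' directions, the held-out fold is predicted, and [dsnr_core()] is
#' evaluated on the held-out predictions. The fold values are averaged.
#'
#' @param dataset a `dsnr_dataset` (or any list with `X` and `V`).
#' @param n_folds number of cross-validation folds (default 6).
#' @param pca_dims retained principal components (default 20; capped at
#'   the number of channels).
#' @return average held-out dSNR.
#' @export
dsnr_cv <- function(dataset, n_folds = 6, pca_dims = 20) {
  X <- as.matrix(dataset$X); V <- as.matrix(dataset$V)
  n <- nrow(X)
  if (n < n_folds) stop("fewer bins than folds", call. = FALSE)
  fold_id <- sort(rep(seq_len(n_folds), length.out = n))  # contiguous blocks
  vals <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold_id == f
    Xtr <- X[!te, , drop = FALSE]; Vtr <- V[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]; Vte <- V[te, , drop = FALSE]
    mu <- colMeans(Xtr)
    Xtr_c <- Xtr - rep(mu, each = nrow(Xtr))
    k <- min(pca_dims, ncol(X), nrow(Xtr) - 1L)
    C <- crossprod(Xtr_c) / (nrow(Xtr) - 1)
    U <- eigen(C, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    Str <- Xtr_c %*% U
    beta <- stats::lm.fit(cbind(1, Str), Vtr)$coefficients
    beta[!is.finite(beta)] <- 0
    Ste <- (Xte - rep(mu, each = nrow(Xte))) %*% U
    pred <- cbind(1, Ste) %*% beta
    vals[f] <- dsnr_core(pred, Vte)
  }
  mean(vals)
}

#' dSNR as a function of channel count
#'
#' Evaluates [dsnr_cv()] on random channel subsets of increasing size:
#' counts range from `min_channels` to the full channel count in steps of
#' `E_N / n_steps` (rounded, duplicates dropped, full count always
#' included), and each count is averaged over `n_subsets` random subsets.
#'
#' @param dataset a `dsnr_dataset`.
#' @param min_channels smallest channel count (default 5).
#' @param n_steps number of steps across the channel range (default 20).
#' @param n_subsets random subsets per count (default 25).
#' @param seed integer seed for subset sampling.
#' @param n_folds,pca_dims passed to [dsnr_cv()].
#' @return object of class `dsnr_curve`: `channel_counts`, `mean_dsnr`,
#'   and the per-repetition table `per_rep` (columns `channel_count`,
#'   `rep`, `dsnr`).
#' @export
dsnr_vs_channels <- function(dataset, min_channels = 5, n_steps = 20,
                             n_subsets = 25, seed = 1L, n_folds = 6,
                             pca_dims = 20) {
  X <- as.matrix(dataset$X)
  en <- ncol(X)
  if (min_channels > en) {
    stop("`min_channels` exceeds the number of channels", call. = FALSE)
  }
  counts <- unique(pmin(round(c(seq(min_channels, en, by = en / n_steps),
                                en)), en))
  set.seed(as.integer(seed))
  per <- vector("list", length(counts))
  means <- numeric(length(counts))
  for (i in seq_along(counts)) {
    nc <- counts[i]
    vals <- numeric(n_subsets)
    for (r in seq_len(n_subsets)) {
      ch <- if (nc == en) seq_len(en) else sample.int(en, nc)
      vals[r] <- dsnr_cv(list(X = X[, ch, drop = FALSE], V = dataset$V),
                         n_folds = n_folds, pca_dims = pca_dims)
    }
    means[i] <- mean(vals)
    per[[i]] <- data.frame(channel_count = nc, rep = seq_len(n_subsets),
                           dsnr = vals)
  }
  structure(list(channel_counts = counts, mean_dsnr = means,
                 per_rep = do.call(rbind, per)),
            class = "dsnr_curve")
}

#' @export
print.dsnr_curve <- function(x, ...) {
  cat(sprintf("<dsnr_curve> %d channel counts (%d..%d), dSNR %.3f..%.3f\n",
              length(x$channel_counts), min(x$channel_counts),
              max(x$channel_counts), min(x$mean_dsnr), max(x$mean_dsnr)))
  invisible(x)
}

#' Power-law fit of a dSNR-versus-channels curve
#'
#' Fits `dSNR = B * N_C^m` by least squares on the log--log points,
#' using only the highest `top_fraction` of the channel counts (default
#' the top 75%), and reports the slope `m`, scale `B` and the `R^2` of
#' the linear fit. Under ideal independent, identically distributed
#' Gaussian channel noise the expected exponent is `m = 0.5`.
#'
#' @param curve a `dsnr_curve` from [dsnr_vs_channels()], or a list with
#'   `channel_counts` and `mean_dsnr`.
#' @param top_fraction fraction of the largest channel counts retained.
#' @return object of class `power_law_fit`: `B`, `m`, `r_squared`,
#'   `channel_counts` (those used).
#' @export
power_law_fit <- function(curve, top_fraction = 0.75) {
  counts <- curve$channel_counts
  dsnr <- curve$mean_dsnr
  stopifnot(length(counts) == length(dsnr))
  keep_n <- max(3L, ceiling(top_fraction * length(counts)))
  ord <- order(counts, decreasing = TRUE)
  keep <- sort(ord[seq_len(min(keep_n, length(counts)))])
  x <- counts[keep]; y <- dsnr[keep]
  if (length(x) < 3) stop("need at least 3 retained points", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("retained dSNR values must be positive and finite", call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  m <- fit$coefficients[2]
  B <- exp(fit$coefficients[1])
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NaN
  structure(list(B = unname(B), m = unname(m), r_squared = r2,
                 channel_counts = x),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> dSNR = %.3g * N^%.3f (R^2 = %.4f, %d pts)\n",
              x$B, x$m, x$r_squared, length(x$channel_counts)))
  invisible(x)
}
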