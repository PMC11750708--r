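#' Create a synthetic SBP population with known velocity tuning
#'
#' Builds a generative tuning model for a multichannel spike-band-power
#' (SBP) population: each channel's mean SBP is an affine function of the
#' instantaneous finger velocity (plus optional pairwise velocity-product
#' interaction terms), with independent, identically distributed Gaussian
#' noise per channel. This is the idealized population assumed by the dSNR
#' channel-scaling theory, and it gives every downstream stage (decoder,
#' tasks, evaluation) a ground truth to be tested against.
#'
#' @param n_channels number of recording channels (default 192, i.e. two
#'   96-channel arrays).
#' @param dof number of velocity degrees of freedom the population is tuned
#'   to (1--4).
#' @param tuning_sd spread of the i.i.d. Gaussian tuning coefficients, in
#'   SBP units per ROM-unit/s. `0` yields an untuned population.
#' @param noise_sd per-channel noise standard deviation (SBP units); scalar
#'   or length-`n_channels` vector.
#' @param interaction_scale spread of gains on pairwise velocity products
#'   (SBP units per (ROM-unit/s)^2). `0` (default) omits interactions, so
#'   the emitted mean is affine in velocity.
#' @param baseline per-channel SBP offset; scalar or vector (default 1).
#' @param seed integer seed; the model is deterministic given its arguments.
#'
#' @return An object of class `sbp_population` with fields `n_channels`,
#'   `dof`, `baseline`, `tuning` (`n_channels x dof`), `interaction`
#'   (`n_channels x choose(dof, 2)` or `NULL`), `noise_sd`, `seed`.
#' @seealso [emit_sbp()], [analytic_participation_ratio()]
#' @export
#' @examples
#' pop <- make_population(n_channels = 24, dof = 2, seed = 1)
#' x <- emit_sbp(pop, c(0.5, -0.5))
make_population <- function(n_channels = 192, dof = 4, tuning_sd = 1,
                            noise_sd = 1, interaction_scale = 0,
                            baseline = 1, seed = 1L) {
  if (length(n_channels) != 1L || n_channels < 1) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  if (length(dof) != 1L || !dof %in% 1:4) {
    stop("`dof` must be 1, 2, 3 or 4", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (tuning_sd < 0) stop("`tuning_sd` must be nonnegative", call. = FALSE)
  n_channels <- as.integer(n_channels)
  dof <- as.integer(dof)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  tuning <- matrix(stats::rnorm(n_channels * dof, sd = max(tuning_sd, 0)),
                   n_channels, dof)
  if (tuning_sd == 0) tuning[] <- 0
  n_pairs <- (dof * (dof - 1L)) %/% 2L
  interaction <- NULL
  if (interaction_scale > 0 && n_pairs > 0) {
    interaction <- matrix(stats::rnorm(n_channels * n_pairs,
                                       sd = interaction_scale),
                          n_channels, n_pairs)
  }
  structure(list(
    n_channels = n_channels,
    dof = dof,
    baseline = rep_len(as.numeric(baseline), n_channels),
    tuning = tuning,
    interaction = interaction,
    noise_sd = rep_len(as.numeric(noise_sd), n_channels),
    seed = as.integer(seed)
  ), class = "sbp_population")
}

#' @export
print.sbp_population <- function(x, ...) {
  cat(sprintf("<sbp_population> %d channels, %d DOF, %s interactions\n",
              x$n_channels, x$dof,
              if (is.null(x$interaction)) "no" else "pairwise"))
  cat(sprintf("  mean |tuning| %.3f, mean noise sd %.3f\n",
              mean(abs(x$tuning)), mean(x$noise_sd)))
  invisible(x)
}

# indices of the pairwise products, column order (1,2),(1,3),...,(d-1,d)
.pair_index <- function(dof) {
  if (dof < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(dof, 2L))
}

.velocity_products <- function(v_mat, dof) {
  idx <- .pair_index(dof)
  if (nrow(idx) == 0) return(NULL)
  out <- matrix(0, nrow(v_mat), nrow(idx))
  for (k in seq_len(nrow(idx))) {
    out[, k] <- v_mat[, idx[k, 1]] * v_mat[, idx[k, 2]]
  }
  out
}

#' Emit one bin of synthetic SBP for a given finger velocity
#'
#' Returns `baseline + tuning %*% velocity` (plus interaction terms when
#' present) with i.i.d. Gaussian channel noise drawn from R's current
#' random-number stream (which is advanced by the call). Seed the stream
#' with [set.seed()] for reproducible emission.
#'
#' @param model an [sbp_population][make_population] model.
#' @param velocity numeric vector of length `model$dof` (ROM-units/s).
#' @return numeric vector of `model$n_channels` SBP values.
#' @export
emit_sbp <- function(model, velocity) {
  stopifnot(inherits(model, "sbp_population"))
  if (length(velocity) != model$dof) {
    stop(sprintf("`velocity` must have length %d (got %d)",
                 model$dof, length(velocity)), call. = FALSE)
  }
  drop(emit_sbp_series(model, matrix(velocity, 1)))
}

#' Emit a series of SBP bins for a velocity time series
#'
#' Vectorized form of [emit_sbp()]: one row of SBP per row of velocity.
#'
#' @param model an [sbp_population][make_population] model.
#' @param velocities `n x dof` matrix of finger velocities (ROM-units/s).
#' @return `n x n_channels` matrix of SBP.
#' @export
emit_sbp_series <- function(model, velocities) {
  stopifnot(inherits(model, "sbp_population"))
  velocities <- as.matrix(velocities)
  if (ncol(velocities) != model$dof) {
    stop(sprintf("`velocities` must have %d columns", model$dof),
         call. = FALSE)
  }
  n <- nrow(velocities)
  mu <- velocities %*% t(model$tuning)
  if (!is.null(model$interaction)) {
    mu <- mu + .velocity_products(velocities, model$dof) %*%
      t(model$interaction)
  }
  mu <- sweep(mu, 2, model$baseline, "+")
  if (any(model$noise_sd > 0)) {
    noise <- matrix(stats::rnorm(n * model$n_channels), n) *
      rep(model$noise_sd, each = n)
    mu <- mu + noise
  }
  mu
}

#' Closed-form participation ratio implied by a linear tuning model
#'
#' For a population whose SBP is `baseline + T v + noise` driven by
#' zero-mean velocities with covariance `velocity_covariance`, the channel
#' covariance is `C = T S T' + diag(noise_sd^2)` and the participation
#' ratio is `(sum lambda)^2 / sum lambda^2 = tr(C)^2 / tr(C^2)`. This is
#' the analytic oracle against which the empirical
#' [participation_ratio()] is validated.
#'
#' When the model carries pairwise interaction terms the closed form is
#' extended under the assumption of independent zero-mean Gaussian
#' velocities (diagonal `velocity_covariance`): the product terms
#' `v_i v_j` are then mutually uncorrelated with the linear terms and with
#' each other, with variance `S_ii S_jj`.
#'
#' @param model an [sbp_population][make_population] model.
#' @param velocity_covariance `dof x dof` symmetric positive semidefinite
#'   matrix (ROM-units/s)^2; a scalar is expanded to `scalar * I`.
#' @return the participation ratio (a number in `[1, n_channels]`).
#' @export
analytic_participation_ratio <- function(model, velocity_covariance) {
  stopifnot(inherits(model, "sbp_population"))
  d <- model$dof
  if (length(velocity_covariance) == 1L) {
    velocity_covariance <- diag(as.numeric(velocity_covariance), d)
  }
  S <- as.matrix(velocity_covariance)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("`velocity_covariance` must be symmetric", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("`velocity_covariance` must be positive semidefinite",
         call. = FALSE)
  }
  C <- model$tuning %*% S %*% t(model$tuning) + diag(model$noise_sd^2,
                                                     model$n_channels)
  if (!is.null(model$interaction)) {
    offdiag <- S - diag(diag(S), d)
    if (max(abs(offdiag)) > 1e-12) {
      stop(paste0("closed form with interaction terms requires a diagonal ",
                  "`velocity_covariance` (independent velocities)"),
           call. = FALSE)
    }
    idx <- .pair_index(d)
    pv <- diag(S)[idx[, 1]] * diag(S)[idx[, 2]]
    C <- C + model$interaction %*% (pv * t(model$interaction))
  }
  sum(diag(C))^2 / sum(C * C)
}

#' Construct a single decoder input window
#'
#' The decoder input is an `n_channels x 3` matrix holding the three most
#' recent 50-ms SBP bins, oldest first.
#'
#' @param values `n_channels x 3` numeric matrix.
#' @return the matrix with class `sbp_window`.
#' @export
sbp_window <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 3L) {
    stop("an SBP window has exactly 3 time bins", call. = FALSE)
  }
  structure(values, class = c("sbp_window", "matrix"))
}

#' Slide a 3-bin window over an SBP series
#'
#' Converts an `n_bins x n_channels` SBP series into the decoder's input
#' windows. Window `t` holds bins `t-2, t-1, t`; the first two bins are
#' padded by repeating the first bin so that every bin of the series has a
#' window and labels stay aligned with bins.
#'
#' @param sbp `n_bins x n_channels` matrix.
#' @param pad pad the first two windows by repeating the first bin
#'   (default `TRUE`); if `FALSE`, windows start at bin 3 and the result
#'   has `n_bins - 2` slices.
#' @return array of dim `c(n_channels, 3, n_windows)`.
#' @export
make_windows <- function(sbp, pad = TRUE) {
  sbp <- as.matrix(sbp)
  n <- nrow(sbp)
  if (pad) sbp <- rbind(sbp[1, , drop = FALSE], sbp[1, , drop = FALSE], sbp)
  n_out <- nrow(sbp) - 2L
  en <- ncol(sbp)
  out <- array(0, c(en, 3L, n_out))
  for (k in 1:3) out[, k, ] <- t(sbp[seq_len(n_out) + k - 1L, , drop = FALSE])
  out
}

# save/restore the global RNG so model construction does not disturb the
# caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
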