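#' Online performance metrics for one trial
#'
#' Standard target-acquisition metrics, computed from the per-bin position
#' log of a trial:
#' * `time_to_target`: cue to the first bin in which all DOF were inside
#'   their targets;
#' * `acquisition_time`: cue to the final target entry, i.e. the start of
#'   the successful hold (the required hold itself is excluded);
#' * `orbiting_time`: their difference -- time spent re-approaching the
#'   target after the first entry;
#' * `path_length_efficiency`: straight-line (net) displacement from the
#'   start to the final-entry position (Euclidean norm over the cued DOF
#'   jointly) divided by the path length actually traversed up to the
#'   final entry -- 1 for a perfectly direct approach;
#' * `fitts_bits`: the Fitts index of difficulty
#'   `sum over cued DOF of log2(D/W + 1)`.
#'
#' By construction `acquisition_time = time_to_target + orbiting_time`
#' exactly. Failed trials return `NA` for the acquisition fields.
#'
#' @param record a `trial_record` from [run_closed_loop_session()].
#' @return list of class `trial_metrics`.
#' @export
trial_metrics <- function(record) {
  if (is.null(record$positions) || record$n_bins < 1) {
    stop("empty trial record", call. = FALSE)
  }
  k <- record$n_bins
  dof <- ncol(record$positions)
  pos <- record$positions[-1L, , drop = FALSE]           # at bin ends
  inside <- abs(pos - rep(record$centers, each = k)) <= record$width / 2
  all_in <- rowSums(inside) == dof
  hold_bins <- round(record$hold_required / BIN_S)
  cued_dof <- .cued_dof(record)
  D <- abs(record$centers - record$positions[1L, ])[cued_dof]
  W <- record$width
  fitts <- sum(log2(D / W + 1))

  success <- isTRUE(record$success)
  t2t <- orbit <- acq <- ple <- NA_real_
  if (any(all_in)) t2t <- (which(all_in)[1L] - 1L) * BIN_S
  if (success) {
    j_end <- k                                  # success fires at bin k
    j0 <- j_end - hold_bins + 1L                # first bin of final streak
    acq <- (j0 - 1L) * BIN_S
    orbit <- acq - t2t
    path_pos <- record$positions[seq_len(j0), cued_dof, drop = FALSE]
    path_len <- if (nrow(path_pos) < 2) 0 else {
      seg <- diff(path_pos)
      sum(sqrt(rowSums(seg^2)))
    }
    # net displacement over traversed path: the triangle inequality keeps
    # this in [0, 1] even though the trial ends at the target edge rather
    # than its center
    straight <- sqrt(sum((path_pos[nrow(path_pos), ] - path_pos[1L, ])^2))
    ple <- if (path_len > 0) min(straight / path_len, 1) else 1
  }
  structure(list(success = success,
                 time_to_target = t2t,
                 orbiting_time = orbit,
                 acquisition_time = acq,
                 path_length_efficiency = ple,
                 fitts_bits = fitts),
            class = "trial_metrics")
}

.cued_dof <- function(record) {
  dof <- ncol(record$positions)
  groups <- finger_groups(dof)
  cg <- record$cued_groups
  if (length(cg) == 0) return(seq_len(dof))
  sort(unique(unlist(groups[cg], use.names = FALSE)))
}

#' Session-level summary metrics
#'
#' Aggregates [trial_metrics()] over a block of trials: mean and standard
#' error (sample SD / sqrt(n)) of each metric over successful trials, the
#' target acquisition rate (successful targets per minute of task time),
#' the percent of trials completed, and Fitts-law throughput -- the mean
#' over successful trials of the index of difficulty divided by the
#' acquisition time (trials acquired instantaneously, e.g. back trials
#' starting on target, contribute no information and are excluded).
#'
#' @param records list of `trial_record`s.
#' @return list of class `session_metrics`.
#' @export
session_metrics <- function(records) {
  stopifnot(length(records) >= 1)
  mets <- lapply(records, trial_metrics)
  succ <- vapply(mets, function(m) m$success, NA)
  total_time_s <- sum(vapply(records, function(r) {
    if (isTRUE(r$success)) r$completion_time else r$timeout
  }, 0))
  msem <- function(field) {
    x <- vapply(mets[succ], function(m) m[[field]], 0)
    x <- x[is.finite(x)]
    if (!length(x)) return(c(mean = NA_real_, sem = NA_real_, n = 0))
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  }
  tp <- vapply(mets[succ], function(m) {
    if (is.finite(m$acquisition_time) && m$acquisition_time > 0) {
      m$fitts_bits / m$acquisition_time
    } else NA_real_
  }, 0)
  tp <- tp[is.finite(tp)]
  structure(list(
    n_trials = length(records),
    n_success = sum(succ),
    percent_complete = 100 * mean(succ),
    targets_per_min = sum(succ) / (total_time_s / 60),
    acquisition_time = msem("acquisition_time"),
    time_to_target = msem("time_to_target"),
    orbiting_time = msem("orbiting_time"),
    path_length_efficiency = msem("path_length_efficiency"),
    throughput_bps = if (length(tp)) {
      c(mean = mean(tp), sem = stats::sd(tp) / sqrt(length(tp)),
        n = length(tp))
    } else c(mean = NA_real_, sem = NA_real_, n = 0)
  ), class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> %d/%d trials (%.1f%%), %.1f targets/min\n",
              x$n_success, x$n_trials, x$percent_complete,
              x$targets_per_min))
  fmt <- function(nm, v, unit) {
    cat(sprintf("  %-24s %.3f +/- %.3f %s (n=%d)\n", nm, v["mean"],
                v["sem"], unit, as.integer(v["n"])))
  }
  fmt("acquisition time", x$acquisition_time, "s")
  fmt("time to target", x$time_to_target, "s")
  fmt("orbiting time", x$orbiting_time, "s")
  fmt("path efficiency", x$path_length_efficiency, "")
  fmt("throughput", x$throughput_bps, "bps")
  invisible(x)
}

#' Finger individuation matrix
#'
#' For blocks in which a single finger group is cued per trial, computes
#' the mean absolute velocity of every group during the Go period
#' (200--700 ms after the cue) of trials cueing group `i`, and normalizes
#' each row by its largest entry. A perfectly individuated decoder gives
#' an identity-like matrix; shared signals inflate the off-diagonal.
#'
#' @param records trial records with a single cued group each.
#' @param go_window Go period relative to the cue (s).
#' @return `group x group` matrix, rows = cued group.
#' @export
individuation <- function(records, go_window = c(0.2, 0.7)) {
  stopifnot(length(records) >= 1)
  dof <- ncol(records[[1]]$positions)
  groups <- finger_groups(dof)
  gnames <- names(groups)
  acc <- matrix(0, length(groups), length(groups),
                dimnames = list(cued = gnames, moved = gnames))
  cnt <- stats::setNames(numeric(length(groups)), gnames)
  for (rec in records) {
    cg <- rec$cued_groups
    if (length(cg) != 1) {
      stop("individuation requires exactly one cued group per trial",
           call. = FALSE)
    }
    bins <- which((seq_len(rec$n_bins) - 1L) * BIN_S >= go_window[1] &
                    seq_len(rec$n_bins) * BIN_S <= go_window[2] + 1e-9)
    if (!length(bins)) next
    v <- abs(rec$decoded[bins, , drop = FALSE])
    gm <- vapply(groups, function(ix) mean(v[, ix]), 0)
    acc[cg, ] <- acc[cg, ] + gm
    cnt[cg] <- cnt[cg] + 1
  }
  keep <- cnt > 0
  acc[keep, ] <- acc[keep, ] / cnt[keep]
  mx <- apply(acc, 1, max)
  acc[keep & mx > 0, ] <- acc[keep & mx > 0, , drop = FALSE] /
    mx[keep & mx > 0]
  acc
}

#' Participation-ratio dimensionality of population activity
#'
#' Mean-centers the activity, forms the channel covariance and returns
#' `PR = (sum lambda)^2 / sum lambda^2` over its eigenvalues -- an
#' effective dimensionality between 1 (a single mode) and the number of
#' channels (isotropic activity).
#'
#' @param activity `n_bins x n_channels` matrix.
#' @return list of class `dimensionality_result` with `eigenvalues` and
#'   `participation_ratio`.
#' @export
participation_ratio <- function(activity) {
  activity <- as.matrix(activity)
  if (nrow(activity) < 2) {
    stop("need at least 2 bins of activity", call. = FALSE)
  }
  xc <- scale(activity, center = TRUE, scale = FALSE)
  C <- crossprod(xc) / (nrow(activity) - 1)
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  structure(list(eigenvalues = lambda,
                 participation_ratio = sum(lambda)^2 / sum(lambda^2)),
            class = "dimensionality_result")
}

#' @export
print.dimensionality_result <- function(x, ...) {
  cat(sprintf("<dimensionality> PR = %.3f over %d eigenvalues\n",
              x$participation_ratio, length(x$eigenvalues)))
  invisible(x)
}

#' Normalized zero-lag cross-correlation between velocity traces
#'
#' Per DOF, the inner product of the two traces divided by the product of
#' their norms (no mean removal), averaged across DOF. Used to compare
#' online decoded velocities with offline re-decoded ones. A DOF with a
#' zero-norm trace is undefined (`NA`) and excluded from the average;
#' the per-DOF values are attached as attribute `"per_dof"`.
#'
#' @param v_a,v_b equal-length vectors or `n x dof` matrices.
#' @return scalar in `[-1, 1]` (or `NA` if undefined for every DOF).
#' @export
normalized_cc <- function(v_a, v_b) {
  a <- as.matrix(v_a); b <- as.matrix(v_b)
  if (!all(dim(a) == dim(b))) stop("traces must match in shape",
                                   call. = FALSE)
  per <- vapply(seq_len(ncol(a)), function(j) {
    na <- sqrt(sum(a[, j]^2)); nb <- sqrt(sum(b[, j]^2))
    if (na == 0 || nb == 0) NA_real_ else sum(a[, j] * b[, j]) / (na * nb)
  }, 0)
  out <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  attr(out, "per_dof") <- per
  out
}
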