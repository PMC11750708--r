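# Shared fixtures, all generated in code. Problem sizes are kept small
# (tens of channels, narrow hidden layers) so the full suite runs quickly
# on one CPU; the science being tested does not depend on the sizes.

quick_population <- function(n_channels = 16, dof = 2, noise_sd = 1,
                             seed = 5, ...) {
  make_population(n_channels, dof, tuning_sd = 1, noise_sd = noise_sd,
                  seed = seed, ...)
}

quick_decoder_config <- function(n_channels, dof, width = 48L) {
  decoder_config(n_channels, dof, hidden_widths = c(width, width, width, dof))
}

# a decoder trained on random smooth velocities from the given population
quick_trained_decoder <- function(model, n = 1200, epochs = 15, seed = 2,
                                  velocity_sd = 0.3, width = 48L) {
  set.seed(seed)
  V <- matrix(stats::rnorm(n * model$dof, sd = velocity_sd), n)
  X <- emit_sbp_series(model, V)
  ts <- training_set(make_windows(X), V)
  train_supervised(init_decoder(quick_decoder_config(model$n_channels,
                                                     model$dof, width),
                                seed = seed),
                   ts, epochs = epochs, seed = seed + 1L)
}

# least-squares oracle: ridge-free pseudo-inverse regression of V on the
# current SBP bin, independent of the decoder's feature path
ols_oracle_predict <- function(X_train, V_train, X_test) {
  Xc <- cbind(1, X_train)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% V_train) / sv$d[keep])
  cbind(1, X_test) %*% beta
}

# hand-built trial record: target at `center` (1 DOF moving, second DOF
# parked inside its target), with an explicit per-bin inside/outside
# schedule for the moving DOF
schedule_record <- function(inside_bins, n_bins, hold_required = 0.5,
                            width = 0.2, center = 0.7, success = TRUE) {
  pos1 <- ifelse(seq_len(n_bins) %in% inside_bins, center, 0.2)
  positions <- cbind(c(0.2, pos1), rep(0.5, n_bins + 1L))
  decoded <- diff(positions) / 0.05
  hold_bins <- round(hold_required / 0.05)
  structure(list(
    task_kind = "cl2d", centers = c(center, 0.5), width = width,
    hold_required = hold_required, timeout = 10,
    cued_groups = c("thumb", "index_middle"), frozen_dof = integer(0),
    is_center = FALSE, cue_time = 0, n_bins = n_bins,
    positions = positions, decoded = decoded,
    intents = matrix(0, n_bins, 2), sbp = matrix(0, n_bins, 2),
    success = success,
    first_entry_time = (min(inside_bins) - 1) * 0.05,
    last_entry_time = if (success) (n_bins - hold_bins) * 0.05 else NA_real_,
    completion_time = if (success) n_bins * 0.05 else NA_real_
  ), class = "trial_record")
}

session_success_rate <- function(records) {
  mean(vapply(records, function(r) isTRUE(r$success), NA))
}
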