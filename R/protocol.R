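#' Run a full simulated experiment from a configuration
#'
#' Executes the standard training-and-evaluation protocol against the
#' synthetic population:
#'
#' 1. generate open-loop blocks and train an initial decoder on the cued
#'    trajectories;
#' 2. run closed-loop training blocks (the `t_train` variant for 4-DOF
#'    configurations, the 2-finger task otherwise), applying a ReFIT
#'    relabel + update after each block, until the block success rate
#'    reaches `schedule$gate_success` or `schedule$training_blocks` is
#'    exhausted;
#' 3. run `schedule$eval_blocks` evaluation blocks on the main task with
#'    the final decoder.
#'
#' Every stage's seed is derived from the global `config$seed`, so the
#' whole session is reproducible. Decoder version ids increase across
#' retraining events.
#'
#' @param config a `session_config` (see [default_config()]).
#' @param out_dir optional directory; when given, writes `config.yaml`,
#'   `decoder.json`, `trials.jsonl` (evaluation blocks) and `metrics.csv`.
#' @param verbose print block-by-block progress.
#' @return list of class `session_log`: `blocks` (each with `task`,
#'   `records`, `decoder_version`, `success_rate`), `decoder`, `model`,
#'   `config`.
#' @export
run_protocol <- function(config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  config <- as_session_config(unclass(config))
  seed <- as.integer(config$seed)
  pop <- config$population
  model <- make_population(pop$n_channels, pop$dof, pop$tuning_sd,
                           pop$noise_sd, pop$interaction_scale,
                           pop$baseline, seed = seed)
  dof <- pop$dof
  dc <- config$decoder
  cfg <- decoder_config(pop$n_channels, dof,
                        n_time_features = dc$n_time_features,
                        hidden_widths = c(dc$hidden_widths[1:3], dof),
                        dropout = dc$dropout,
                        speed_constant = dc$speed_constant)
  dec <- init_decoder(cfg, seed = seed + 1L)

  set.seed(seed + 2L)
  block <- open_loop_block(dof, n_pairs = config$schedule$open_loop_pairs)
  tset <- build_open_loop_training(model, block, seed = seed + 3L)
  dec <- train_supervised(dec, tset, epochs = dc$epochs,
                          learning_rate = dc$learning_rate,
                          batch_size = dc$batch_size, seed = seed + 4L)

  train_task <- if (dof == 4) task_config("t_train") else {
    task_config(config$task$kind, config$task$width,
                config$task$hold_required, config$task$timeout,
                config$task$user_speed, config$task$motor_noise_sd)
  }
  eval_task <- task_config(config$task$kind, config$task$width,
                           config$task$hold_required, config$task$timeout,
                           config$task$user_speed,
                           config$task$motor_noise_sd)
  blocks <- list()
  gate <- config$schedule$gate_success
  for (b in seq_len(config$schedule$training_blocks)) {
    recs <- run_closed_loop_session(train_task, dec, model,
                                    n_trials = config$schedule$closed_loop_trials,
                                    seed = seed + 10L + b)
    sr <- mean(vapply(recs, function(r) r$success, NA))
    blocks[[length(blocks) + 1L]] <-
      list(task = train_task$kind, phase = "training", records = recs,
           decoder_version = dec$version, success_rate = sr)
    if (verbose) {
      message(sprintf("training block %d (%s): %.0f%% success", b,
                      train_task$kind, 100 * sr))
    }
    rl <- refit_relabel(recs)
    dec <- refit_update(dec, rl, seed = seed + 100L + b)
    if (sr >= gate) break
  }
  eval_records <- list()
  for (b in seq_len(config$schedule$eval_blocks)) {
    recs <- run_closed_loop_session(eval_task, dec, model,
                                    n_trials = config$schedule$closed_loop_trials,
                                    seed = seed + 200L + b)
    sr <- mean(vapply(recs, function(r) r$success, NA))
    blocks[[length(blocks) + 1L]] <-
      list(task = eval_task$kind, phase = "evaluation", records = recs,
           decoder_version = dec$version, success_rate = sr)
    eval_records <- c(eval_records, recs)
    if (verbose) {
      message(sprintf("evaluation block %d (%s): %.0f%% success", b,
                      eval_task$kind, 100 * sr))
    }
  }
  log <- structure(list(blocks = blocks, decoder = dec, model = model,
                        config = config), class = "session_log")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_config(config, file.path(out_dir, "config.yaml"))
    save_decoder(dec, file.path(out_dir, "decoder.json"))
    if (length(eval_records)) {
      write_trial_log(eval_records, file.path(out_dir, "trials.jsonl"))
      write_metrics_csv(eval_records, file.path(out_dir, "metrics.csv"))
    }
  }
  log
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d blocks, final decoder v%d\n",
              length(x$blocks), x$decoder$version))
  for (b in x$blocks) {
    cat(sprintf("  %-10s %-14s v%d  %.0f%% success\n", b$phase, b$task,
                b$decoder_version, 100 * b$success_rate))
  }
  invisible(x)
}
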