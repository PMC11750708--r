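#' Default session configuration
#'
#' A nested configuration covering every stage of a simulated experiment:
#' population, task, decoder, training schedule, quadcopter mapping and
#' the global seed (from which every component seed is derived). The
#' training schedule mirrors the standard protocol: open-loop blocks
#' first, then closed-loop training blocks (the `t_train` variant for 4
#' DOF) with a ReFIT update after each block until the block success rate
#' reaches `gate_success`, then evaluation blocks on the main task.
#'
#' @return nested list of class `session_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    population = list(n_channels = 192L, dof = 2L, tuning_sd = 1,
                      noise_sd = 1, interaction_scale = 0, baseline = 1),
    task = list(kind = "cl2d", width = 0.2, hold_required = 0.5,
                timeout = 10, user_speed = 0.6, motor_noise_sd = 0.05),
    decoder = list(n_time_features = 16L,
                   hidden_widths = c(256L, 256L, 256L, 2L),
                   dropout = 0.5, speed_constant = 1,
                   epochs = 60L, learning_rate = 1e-3, batch_size = 64L),
    schedule = list(open_loop_pairs = 12L, closed_loop_trials = 20L,
                    training_blocks = 2L, eval_blocks = 1L,
                    gate_success = 0.8),
    quadcopter = list(gains = c(thumb_flex = 0.6, thumb_abd = 0.8,
                                index_middle = 0.4, ring_little = 0.6),
                      max_linear_speed = 10, max_yaw_rate = 90,
                      neutral_zone = 0.1, gravity_amplitude = 0.05)
  ), class = "session_config")
}

.validate_config <- function(cfg, defaults = default_config(),
                             path = character(0)) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ",
         paste(c(path, unknown[1]), collapse = "$"), call. = FALSE)
  }
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- .validate_config(cfg[[nm]], defaults[[nm]],
                                    c(path, nm))
    }
  }
  cfg
}

#' Load, validate and save session configurations
#'
#' Configurations are stored as YAML. Loading fills defaults for missing
#' fields, rejects unknown fields, and checks cross-field invariants
#' (e.g. `task$hold_required <= task$timeout`).
#'
#' @param path file path.
#' @return a validated `session_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_session_config(raw)
}

#' @rdname load_config
#' @param x a bare named list.
#' @export
as_session_config <- function(x) {
  cfg <- .validate_config(x)
  if (cfg$task$hold_required > cfg$task$timeout) {
    stop("task$hold_required exceeds task$timeout", call. = FALSE)
  }
  if (cfg$population$dof != cfg$decoder$hidden_widths[4]) {
    cfg$decoder$hidden_widths[4] <- cfg$population$dof
  }
  # YAML drops vector names; restore the canonical DOF order
  cfg$quadcopter$gains <- stats::setNames(
    unlist(cfg$quadcopter$gains, use.names = FALSE),
    names(default_config()$quadcopter$gains))
  cm <- cfg$quadcopter
  control_mapping(cm$gains, cm$max_linear_speed, cm$max_yaw_rate,
                  cm$neutral_zone, cm$gravity_amplitude)  # validates
  structure(cfg, class = "session_config")
}

#' @rdname load_config
#' @param config a `session_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- matrix-preserving JSON helpers -----------------------------------

.pack_value <- function(x) {
  if (is.matrix(x)) {
    list(.mat = TRUE, dim = dim(x), data = as.vector(x))
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, .pack_value)
  } else x
}

.unpack_value <- function(x) {
  if (is.list(x) && isTRUE(x$.mat)) {
    matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
  } else if (is.list(x)) {
    lapply(x, .unpack_value)
  } else x
}

#' Trial logs as JSON-lines
#'
#' One trial per line; per-bin matrices are stored inline with their
#' dimensions so that reading returns records equal to the written ones
#' field for field. `read_trial_log` reports the line number of any
#' malformed line.
#'
#' @param records list of `trial_record`s.
#' @param path file path (`.jsonl`).
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the list of records.
#' @export
write_trial_log <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    line <- jsonlite::toJSON(.pack_value(unclass(rec)), digits = NA,
                             auto_unbox = FALSE, null = "null")
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                         simplifyMatrix = FALSE),
      error = function(e) {
        stop(sprintf("malformed trial log line %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    rec <- .unpack_value(parsed)
    rec <- lapply(rec, function(x) {
      if (is.list(x) && !is.matrix(x)) unlist(x) else x
    })
    # scalars come back as length-1 vectors; restore types
    rec$success <- isTRUE(as.logical(rec$success))
    rec$is_center <- isTRUE(as.logical(rec$is_center))
    rec$n_bins <- as.integer(rec$n_bins)
    rec$frozen_dof <- as.integer(rec$frozen_dof)
    if (is.null(rec$cued_groups)) rec$cued_groups <- character(0)
    class(rec) <- "trial_record"
    out[[i]] <- rec
  }
  out
}

#' Serialize decoder parameters and tuning models
#'
#' Plain-text JSON containers with a format version field; matrices are
#' stored with their dimensions and full double precision.
#'
#' @param params a `finger_decoder`.
#' @param path file path (`.json`).
#' @export
save_decoder <- function(params, path) {
  stopifnot(inherits(params, "finger_decoder"))
  obj <- list(format = "fingerbci_decoder", format_version = 1L,
              payload = .pack_value(unclass(params)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "fingerbci_decoder")) {
    stop("not a decoder file: ", path, call. = FALSE)
  }
  p <- .unpack_value(obj$payload)
  p$config <- lapply(p$config, function(x) if (is.list(x)) unlist(x) else x)
  class(p$config) <- "decoder_config"
  for (nm in c("bt", "b1", "b2", "b3", "out_mean", "out_sd", "gains")) {
    if (!is.null(p[[nm]])) p[[nm]] <- unlist(p[[nm]])
  }
  for (nm in grep("^bn", names(p), value = TRUE)) {
    p[[nm]] <- lapply(p[[nm]], function(x) if (is.null(x)) NULL else unlist(x))
  }
  p$version <- as.integer(unlist(p$version))
  class(p) <- "finger_decoder"
  p
}

#' @rdname save_decoder
#' @param model an `sbp_population`.
#' @export
save_population <- function(model, path) {
  stopifnot(inherits(model, "sbp_population"))
  obj <- list(format = "fingerbci_population", format_version = 1L,
              payload = .pack_value(unclass(model)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_population <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "fingerbci_population")) {
    stop("not a population file: ", path, call. = FALSE)
  }
  p <- .unpack_value(obj$payload)
  for (nm in c("baseline", "noise_sd")) p[[nm]] <- unlist(p[[nm]])
  p$n_channels <- as.integer(unlist(p$n_channels))
  p$dof <- as.integer(unlist(p$dof))
  p$seed <- as.integer(unlist(p$seed))
  class(p) <- "sbp_population"
  p
}

#' Write per-trial metrics to CSV
#'
#' One row per trial with the [trial_metrics()] fields; a summary row per
#' block is available from [session_metrics()].
#'
#' @param records list of `trial_record`s.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  rows <- lapply(seq_along(records), function(i) {
    m <- trial_metrics(records[[i]])
    data.frame(trial = i, task = records[[i]]$task_kind,
               success = m$success,
               time_to_target = m$time_to_target,
               orbiting_time = m$orbiting_time,
               acquisition_time = m$acquisition_time,
               path_length_efficiency = m$path_length_efficiency,
               fitts_bits = m$fitts_bits)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a dSNR curve to CSV
#'
#' Long format: one row per (channel count, repetition).
#'
#' @param curve a `dsnr_curve`.
#' @param path output CSV path.
#' @export
write_dsnr_csv <- function(curve, path) {
  utils::write.csv(curve$per_rep, path, row.names = FALSE)
  invisible(path)
}
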