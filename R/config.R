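rate_layer_kinds <- c("feedback_esn", "nofeedback_esn", "constrained_esn")
spiking_layer_kinds <- c("lif", "izhikevich", "theta")
trainer_kinds <- c("force", "full_force", "spiking", "bio_force")
task_generators <- c("sum_of_sines", "lorenz", "delayed_response",
                     "synthetic_recording")

config_schema <- list(
  top = c("seed", "task", "layer", "trainer", "output"),
  task = c("generator", "path", "params"),
  layer = c("kind", "n_neurons", "params"),
  trainer = c("kind", "alpha", "epochs", "update_interval", "warmup_steps",
              "train_output", "train_recurrent", "early_stopping", "params"),
  output = c("downsample", "save", "weights_format")
)

reject_unknown <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  check_that(length(unknown) == 0L,
             sprintf("unknown key%s in %s: %s",
                     if (length(unknown) > 1) "s" else "", where,
                     paste(unknown, collapse = ", ")))
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON experiment description with four blocks — `task`
#' (generator name and parameters, or a saved-task path), `layer` (kind and
#' size), `trainer` (algorithm and RLS settings) and optional `output` —
#' plus a mandatory `seed`. Defaults are filled (alpha = 1,
#' update_interval = 1, warmup_steps = 0, epochs = 10), unknown keys are
#' rejected by name, and incompatible layer/trainer pairings (e.g. the
#' spiking trainer with a rate layer, or classic recurrent FORCE with a
#' multi-dimensional output) raise an error naming both kinds.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `experiment_config` list.
#' @export
load_config <- function(path) {
  check_that(file.exists(path), sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw Named list with the structure described in [load_config()].
#' @return A validated `experiment_config` with defaults filled.
#' @export
validate_config <- function(raw) {
  check_that(is.list(raw), "config must be a mapping")
  reject_unknown(raw, config_schema$top, "config")
  for (field in c("seed", "task", "layer", "trainer")) {
    check_that(!is.null(raw[[field]]),
               sprintf("required config field '%s' is missing", field))
  }
  reject_unknown(raw$task, config_schema$task, "task block")
  reject_unknown(raw$layer, config_schema$layer, "layer block")
  reject_unknown(raw$trainer, config_schema$trainer, "trainer block")
  if (!is.null(raw$output)) {
    reject_unknown(raw$output, config_schema$output, "output block")
  }

  if (is.null(raw$task$path)) {
    check_that(!is.null(raw$task$generator) &&
                 raw$task$generator %in% task_generators,
               sprintf("unknown task generator '%s' (registered: %s)",
                       raw$task$generator %||% "<missing>",
                       paste(task_generators, collapse = ", ")))
  } else {
    check_that(dir.exists(raw$task$path),
               sprintf("task path '%s' does not exist", raw$task$path))
  }

  lk <- raw$layer$kind
  check_that(!is.null(lk) && lk %in% c(rate_layer_kinds, spiking_layer_kinds),
             sprintf("unknown layer kind '%s' (registered: %s)",
                     lk %||% "<missing>",
                     paste(c(rate_layer_kinds, spiking_layer_kinds),
                           collapse = ", ")))
  tk <- raw$trainer$kind
  check_that(!is.null(tk) && tk %in% trainer_kinds,
             sprintf("unknown trainer kind '%s' (registered: %s)",
                     tk %||% "<missing>",
                     paste(trainer_kinds, collapse = ", ")))

  pairing_ok <- switch(tk,
    force = lk %in% c("feedback_esn", "nofeedback_esn"),
    full_force = lk == "nofeedback_esn",
    spiking = lk %in% spiking_layer_kinds,
    bio_force = lk == "constrained_esn"
  )
  check_that(pairing_ok,
             sprintf("trainer '%s' cannot train layer kind '%s'", tk, lk))

  raw$trainer$alpha <- raw$trainer$alpha %||% 1
  raw$trainer$epochs <- raw$trainer$epochs %||% 10L
  raw$trainer$update_interval <- raw$trainer$update_interval %||% 1L
  raw$trainer$warmup_steps <- raw$trainer$warmup_steps %||% 0L
  raw$trainer$train_output <- raw$trainer$train_output %||% TRUE
  raw$trainer$train_recurrent <- raw$trainer$train_recurrent %||% FALSE
  raw$output <- raw$output %||% list()
  raw$output$downsample <- raw$output$downsample %||% 1L
  raw$output$weights_format <- raw$output$weights_format %||% "csv"
  raw$output$save <- raw$output$save %||%
    c("history", "outputs", "weights", "config", "log")
  raw$task$params <- raw$task$params %||% list()
  raw$layer$params <- raw$layer$params %||% list()

  if (isTRUE(raw$trainer$train_recurrent) && tk == "force") {
    m_out <- raw$task$params$m_out %||% 1L
    check_that(m_out == 1L,
               "classic recurrent FORCE supports scalar outputs only")
  }
  structure(raw, class = "experiment_config")
}

#' Write an experiment configuration as YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
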