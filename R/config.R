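#' Experiment configuration
#'
#' `default_config()` returns the full default configuration of the benchmark;
#' `load_config()` reads a YAML or JSON file, fills unspecified fields with the
#' defaults, validates, and rejects unknown keys (suggesting the closest known
#' key). An empty file yields the full default configuration.
#'
#' Sections: `simulator` (selectivity and noise/drift/jump parameters plus the
#' schedule seeds), `network` (`f_density`, learning rates), `classifier`
#' (`n_components`, `scale`), `experiment` (`n_trials`, fault `window`,
#' `master_seed`).
#'
#' @return a nested named list of class `glom_config`
#' @export
default_config <- function() {
  m <- default_array_model()
  structure(list(
    simulator = list(
      selectivity = m$selectivity,
      replicas_per_class = m$replicas_per_class,
      replica_gain_sd = m$replica_gain_sd,
      drift_step_sd = m$drift_step_sd,
      class_drift_correlation = m$class_drift_correlation,
      jump_prob = m$jump_prob,
      jump_sd = m$jump_sd,
      noise_sd = m$noise_sd,
      training_counts = c(40L, 50L, 20L, 20L, 20L),
      testing_episodes = NULL,
      data_seed = 1L),
    network = list(
      f_density = 0.5,
      gamma_a = 5 * 10^-0.7, gamma_b = 10^-0.7,
      delta_a = 10^-0.6, delta_b = 5 * 10^-0.6),
    classifier = list(n_components = 4L, scale = FALSE),
    experiment = list(n_trials = 20L, window = c(400L, 520L),
                      sweep_window = c(250L, 650L),
                      fault_channel = 4L, master_seed = 1L)
  ), class = "glom_config")
}

#' @rdname default_config
#' @details `case_study_config()` is the default configuration for the
#'   single-sensor fault case study: identical to `default_config()` but with
#'   gentler drift and jumps (`drift_step_sd = 0.001`, `jump_sd = 0.03`), so
#'   that the injected fault — not background instability — dominates the
#'   recorded weight and output trajectories, and with a testing schedule of 36
#'   short (20-sample) episodes cycling irregularly through all stimuli, so
#'   the monitored sensor is driven through its full response range around the
#'   fault window (the episode just before the default window is its class's
#'   strong stimulus, giving a well-developed weight for the decay to act on).
#' @export
case_study_config <- function() {
  cfg <- default_config()
  cfg$simulator$drift_step_sd <- 0.001
  cfg$simulator$jump_sd <- 0.03
  stim_order <- c(3, 5, 2, 4, 1, 5, 3, 4, 2, 5, 1, 4, 1, 5, 2, 4, 3, 5,
                  4, 2, 5, 1, 3, 5, 4, 2, 5, 3, 4, 5, 1, 4, 2, 5, 3, 4)
  cfg$simulator$testing_episodes <- lapply(stim_order, function(s) c(s, 20L))
  cfg
}

#' @rdname default_config
#' @param path path to a YAML or JSON configuration file
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(txt)
  }
  cfg <- default_config()
  if (is.null(user) || length(user) == 0) return(cfg)
  problems <- character()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) {
      problems <- c(problems, unknown_key_msg(sec, names(cfg)))
      next
    }
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        problems <- c(problems, unknown_key_msg(paste0(sec, ".", key),
                                                names(cfg[[sec]]), sec))
      } else {
        val <- user[[sec]][[key]]
        if (is.list(val) || (is.vector(val) && !is.null(dim(cfg[[sec]][[key]]))))
          val <- as.matrix(if (is.list(val)) do.call(rbind, val) else val)
        cfg[[sec]][[key]] <- val
      }
    }
  }
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  validate_config(cfg)
  cfg
}

unknown_key_msg <- function(key, known, prefix = NULL) {
  base <- sub(".*\\.", "", key)
  d <- utils::adist(base, known)
  hint <- if (min(d) <= 3) {
    sugg <- known[which.min(d)]
    if (!is.null(prefix)) sugg <- paste0(prefix, ".", sugg)
    sprintf(" (did you mean '%s'?)", sugg)
  } else ""
  sprintf("unknown key '%s'%s", key, hint)
}

validate_config <- function(cfg) {
  sim <- cfg$simulator
  # constructor performs the numeric validation
  sensor_array_model(selectivity = as.matrix(sim$selectivity),
                     replicas_per_class = sim$replicas_per_class,
                     replica_gain_sd = sim$replica_gain_sd,
                     drift_step_sd = sim$drift_step_sd,
                     class_drift_correlation = as.matrix(sim$class_drift_correlation),
                     jump_prob = sim$jump_prob, jump_sd = sim$jump_sd,
                     noise_sd = sim$noise_sd)
  net <- cfg$network
  if (net$f_density < 0 || net$f_density > 1)
    stop("network.f_density must be in [0, 1]")
  if (any(unlist(net[c("gamma_a", "gamma_b", "delta_a", "delta_b")]) <= 0))
    stop("learning rates must be positive")
  if (cfg$experiment$n_trials < 1) stop("experiment.n_trials must be >= 1")
  invisible(cfg)
}

#' Build the simulator model described by a configuration
#'
#' @param cfg a `glom_config`
#' @return a `sensor_array_model`
#' @export
config_model <- function(cfg) {
  sim <- cfg$simulator
  sensor_array_model(selectivity = as.matrix(sim$selectivity),
                     replicas_per_class = sim$replicas_per_class,
                     replica_gain_sd = sim$replica_gain_sd,
                     drift_step_sd = sim$drift_step_sd,
                     class_drift_correlation = as.matrix(sim$class_drift_correlation),
                     jump_prob = sim$jump_prob, jump_sd = sim$jump_sd,
                     noise_sd = sim$noise_sd)
}

#' Network-argument list described by a configuration
#'
#' @param cfg a `glom_config`
#' @return list suitable for the `network_args` argument of the experiment
#'   drivers
#' @export
config_network_args <- function(cfg) {
  list(f_density = cfg$network$f_density,
       learning_rates = c(gamma_a = cfg$network$gamma_a,
                          gamma_b = cfg$network$gamma_b,
                          delta_a = cfg$network$delta_a,
                          delta_b = cfg$network$delta_b))
}

#' Generate the default benchmark data pair
#'
#' Simulates the training phase (150 samples, stimuli interleaved in a rapid
#' irregular sequence) and the testing phase (706 samples in 13 single-stimulus
#' episodes) from one seed; the test stream's sample indices continue the
#' training stream's and drift continues across the phase boundary via a
#' shared simulation of the concatenated schedule.
#'
#' @param cfg a `glom_config` (default [default_config()])
#' @param seed data seed (default taken from the config)
#' @return list with `train` and `test` `response_matrix` objects
#' @export
benchmark_data <- function(cfg = default_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$simulator$data_seed
  model <- config_model(cfg)
  tr_sch <- make_training_schedule(cfg$simulator$training_counts, seed = seed)
  te_sch <- if (is.null(cfg$simulator$testing_episodes)) {
    default_testing_schedule()
  } else {
    make_testing_schedule(cfg$simulator$testing_episodes,
                          n_stimuli = length(cfg$simulator$training_counts))
  }
  full <- concat_schedules(tr_sch, te_sch)
  resp <- simulate_responses(model, full, seed = seed)
  n_tr <- nrow(tr_sch)
  list(train = subset_samples(resp, seq_len(n_tr)),
       test = subset_samples(resp, (n_tr + 1):nrow(full)))
}
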