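#' Synthetic drifting sensor-array model
#'
#' Describes a gas-sensor array of `n_classes` sensor classes with
#' `replicas_per_class` replica sensors per class (default 4 x 4 = 16
#' channels). The clean response of a class to a stimulus is given by the
#' `selectivity` matrix; on top of it the simulator superimposes the
#' instabilities that dominate real metal-oxide arrays:
#'
#' * a fixed multiplicative per-replica gain, `1 + Normal(0, replica_gain_sd)`,
#'   drawn once per channel (manufacturing spread between replicas);
#' * a slow additive baseline drift: per-class Gaussian random walk with
#'   per-sample step sd `drift_step_sd` and cross-class step correlation
#'   `class_drift_correlation` (drift is strongly correlated within a class —
#'   all replicas share it — and partially correlated across classes);
#' * abrupt jumps: at each episode boundary, with probability `jump_prob`, the
#'   class baseline takes an additional `Normal(0, jump_sd)` step shared by all
#'   replicas of the class;
#' * i.i.d. measurement noise `Normal(0, noise_sd)` per entry.
#'
#' Responses are clipped to `[0, 1]` so that the network weights and the fault
#' modes operate on a common normalised scale.
#'
#' @param selectivity numeric matrix, class x stimulus, entries in `[0, 1]`:
#'   mean clean response of a sensor class to each stimulus.
#' @param replicas_per_class integer, replicas per sensor class.
#' @param replica_gain_sd sd of the fixed per-replica gain deviation.
#' @param drift_step_sd per-sample sd of the baseline random-walk step.
#' @param class_drift_correlation symmetric positive-semidefinite matrix with
#'   unit diagonal: correlation of drift steps across classes.
#' @param jump_prob probability of a baseline jump at each episode boundary.
#' @param jump_sd sd of a jump step.
#' @param noise_sd sd of per-entry i.i.d. measurement noise.
#' @return an object of class `sensor_array_model`
#' @export
sensor_array_model <- function(selectivity,
                               replicas_per_class = 4L,
                               replica_gain_sd = 0.05,
                               drift_step_sd = 0.002,
                               class_drift_correlation = NULL,
                               jump_prob = 0.6,
                               jump_sd = 0.08,
                               noise_sd = 0.02) {
  selectivity <- as.matrix(selectivity)
  C <- nrow(selectivity)
  if (any(!is.finite(selectivity)) || any(selectivity < 0) || any(selectivity > 1))
    stop("'selectivity' entries must be finite and in [0, 1]")
  if (is.null(class_drift_correlation)) class_drift_correlation <- diag(C)
  R <- as.matrix(class_drift_correlation)
  if (nrow(R) != C || ncol(R) != C || any(abs(R - t(R)) > 1e-12) ||
      any(abs(diag(R) - 1) > 1e-12))
    stop("'class_drift_correlation' must be symmetric class x class with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("'class_drift_correlation' must be positive semidefinite")
  pars <- c(replica_gain_sd = replica_gain_sd, drift_step_sd = drift_step_sd,
            jump_prob = jump_prob, jump_sd = jump_sd, noise_sd = noise_sd)
  if (any(!is.finite(pars)) || any(pars < 0) || jump_prob > 1)
    stop("sd parameters must be finite non-negative; 'jump_prob' in [0, 1]")
  structure(list(selectivity = selectivity,
                 n_classes = C,
                 n_stimuli = ncol(selectivity),
                 replicas_per_class = as.integer(replicas_per_class),
                 replica_gain_sd = replica_gain_sd,
                 drift_step_sd = drift_step_sd,
                 class_drift_correlation = R,
                 jump_prob = jump_prob, jump_sd = jump_sd,
                 noise_sd = noise_sd),
            class = "sensor_array_model")
}

#' Default 4 x 4 array model
#'
#' Selectivity (4 classes x 5 stimuli) is chosen so that stimulus 1 is clearly
#' distinct (one class responds strongly, the others weakly) while stimuli 2-5
#' overlap across classes, and cross-class drift is strongly correlated between
#' classes 2 and 4 (0.8), moderately with class 3 (0.5) and weakly with class 1
#' (0.3).
#'
#' @param ... overrides passed to [sensor_array_model()]
#' @return a `sensor_array_model`
#' @export
default_array_model <- function(...) {
  sel <- rbind(
    c(0.90, 0.55, 0.50, 0.45, 0.52),
    c(0.20, 0.70, 0.55, 0.60, 0.50),
    c(0.30, 0.50, 0.70, 0.55, 0.60),
    c(0.15, 0.55, 0.50, 0.65, 0.58))
  R <- rbind(c(1.0, 0.3, 0.3, 0.3),
             c(0.3, 1.0, 0.5, 0.8),
             c(0.3, 0.5, 1.0, 0.5),
             c(0.3, 0.8, 0.5, 1.0))
  args <- list(selectivity = sel, class_drift_correlation = R)
  over <- list(...)
  args[names(over)] <- over
  do.call(sensor_array_model, args)
}

#' Simulate sensor-array responses to a stimulus schedule
#'
#' For sample t with stimulus s, channel (class c, replica q):
#' `value = clip_[0,1]( selectivity[c, s] * g_q + b_c(t) + jump_c(t) + eps )`,
#' with the gain, drift, jump and noise processes described in
#' [sensor_array_model()]. All randomness is controlled by `seed`; identical
#' `(model, schedule, seed)` give bit-identical output.
#'
#' @param model a `sensor_array_model`
#' @param schedule a `stim_schedule` (non-empty)
#' @param seed integer seed
#' @param sample_index_start sample index of the first row (default 1); used to
#'   emit test streams whose indices continue a training stream.
#' @return a `response_matrix` with attribute `drift` (samples x classes
#'   cumulative drift+jump baseline, useful for diagnostics)
#' @export
simulate_responses <- function(model, schedule, seed = 1L,
                               sample_index_start = 1L) {
  stopifnot(inherits(model, "sensor_array_model"),
            inherits(schedule, "stim_schedule"))
  n <- nrow(schedule)
  if (n == 0L) stop("'schedule' must be non-empty")
  if (attr(schedule, "n_stimuli") > model$n_stimuli)
    stop("schedule has more stimuli than the model's selectivity matrix")
  C <- model$n_classes; Q <- model$replicas_per_class
  N <- C * Q
  set.seed(as.integer(seed))
  # draw order is part of the determinism contract:
  # gains, drift steps, jump bernoullis, jump sizes, noise
  gains <- 1 + stats::rnorm(N, 0, model$replica_gain_sd)
  steps <- matrix(stats::rnorm(n * C, 0, model$drift_step_sd), n, C)
  U <- chol(model$class_drift_correlation)
  b <- apply(steps %*% U, 2, cumsum)
  if (n == 1L) b <- matrix(b, 1L, C)
  boundary <- c(FALSE, diff(schedule$episode) != 0)
  nb <- sum(boundary)
  jump <- matrix(0, n, C)
  if (nb > 0) {
    occurs <- matrix(stats::runif(nb * C) < model$jump_prob, nb, C)
    sizes <- matrix(stats::rnorm(nb * C, 0, model$jump_sd), nb, C) * occurs
    jsteps <- matrix(0, n, C)
    jsteps[boundary, ] <- sizes
    jump <- apply(jsteps, 2, cumsum)
    if (n == 1L) jump <- matrix(jump, 1L, C)
  }
  eps <- matrix(stats::rnorm(n * N, 0, model$noise_sd), n, N)
  channel_class <- rep(seq_len(C), each = Q)
  clean <- model$selectivity[, schedule$stimulus, drop = FALSE] # C x n
  base <- b + jump                                              # n x C
  vals <- t(clean)[, channel_class, drop = FALSE]               # n x N
  vals <- sweep(vals, 2, gains, `*`) + base[, channel_class, drop = FALSE] + eps
  vals <- pmin(pmax(vals, 0), 1)
  out <- response_matrix(vals, schedule$stimulus, schedule$episode,
                         channel_class,
                         seq_len(n) + as.integer(sample_index_start) - 1L)
  attr(out, "drift") <- base
  out
}

#' Sensor-fault specification
#'
#' A fault affects one channel over a half-open window of sample indices
#' `[start, stop)`. Mode `"dropout"` sets the channel to 0 (complete loss of
#' function); mode `"random"` replaces it with i.i.d. `Uniform(0, 1)` draws
#' (random fluctuations with mean 0.5, spanning the normalised response range).
#'
#' @param channel integer channel index
#' @param start first affected sample index (inclusive)
#' @param stop first unaffected sample index (exclusive); `start < stop`
#' @param mode `"dropout"` or `"random"`
#' @return an object of class `fault_spec`
#' @export
fault_spec <- function(channel, start, stop, mode = c("dropout", "random")) {
  mode <- match.arg(mode)
  channel <- as.integer(channel); start <- as.integer(start); stop <- as.integer(stop)
  if (start >= stop && !(start == stop)) stop("'start' must be < 'stop'")
  structure(list(channel = channel, start = start, stop = stop, mode = mode),
            class = "fault_spec")
}

#' Inject a sensor fault into a response table
#'
#' @param data a `response_matrix`
#' @param fault a `fault_spec`; the window refers to `data$sample_index`
#' @param seed seed for the random-mode replacement draws
#' @return a copy of `data` with the faulty channel overwritten inside the
#'   window; every other entry is bit-identical to the input
#' @export
apply_fault <- function(data, fault, seed = 1L) {
  stopifnot(inherits(data, "response_matrix"), inherits(fault, "fault_spec"))
  if (fault$channel < 1 || fault$channel > ncol(data$values))
    stop("fault channel out of range")
  rows <- which(data$sample_index >= fault$start & data$sample_index < fault$stop)
  if (length(rows) == 0L) {
    if (fault$start != fault$stop)
      warning("fault window overlaps no samples; data returned unchanged")
    return(data)
  }
  out <- data
  if (fault$mode == "dropout") {
    out$values[rows, fault$channel] <- 0
  } else {
    set.seed(as.integer(seed))
    out$values[rows, fault$channel] <- stats::runif(length(rows))
  }
  out
}
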