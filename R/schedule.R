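#' Stimulus schedules
#'
#' A stimulus schedule is the ordered list of stimulus presentations fed to a
#' sensor array: each entry is one exposure, carrying the stimulus identity and
#' an episode id. The training phase presents stimuli individually in a rapid,
#' irregular (randomly interleaved) sequence and carries episode id 0; the
#' testing phase consists of longer episodes of repeated applications of a
#' single stimulus, with episode ids increasing by one per episode.
#'
#' @param counts integer vector of length S: number of presentations of each
#'   stimulus during training. The defaults used throughout the package are
#'   `c(40, 50, 20, 20, 20)` for five stimuli.
#' @param seed integer seed controlling the random interleaving.
#' @return An object of class `stim_schedule`: a data.frame with columns
#'   `stimulus` and `episode`, plus attribute `n_stimuli`.
#' @examples
#' sch <- make_training_schedule(c(40, 50, 20, 20, 20), seed = 1)
#' table(sch$stimulus)
#' @export
make_training_schedule <- function(counts, seed = 1L) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || anyNA(counts) || any(counts < 0L))
    stop("'counts' must be non-negative integers")
  labels <- rep(seq_along(counts), times = counts)
  if (length(labels) > 0L) {
    set.seed(as.integer(seed))
    labels <- labels[sample.int(length(labels))]
  }
  new_schedule(labels, rep(0L, length(labels)), n_stimuli = length(counts))
}

#' @rdname make_training_schedule
#' @param episodes list of episodes, each a pair/list `c(stimulus_id,
#'   n_repetitions)`, applied in the given order.
#' @param first_episode_id episode id assigned to the first episode; subsequent
#'   episodes increment by one.
#' @param n_stimuli number of distinct stimuli S (defaults to the largest
#'   stimulus id appearing in `episodes`).
#' @export
make_testing_schedule <- function(episodes, first_episode_id = 1L,
                                  n_stimuli = NULL) {
  if (length(episodes) == 0L) stop("'episodes' must be non-empty")
  stim <- vapply(episodes, function(e) as.integer(e[[1]]), integer(1))
  reps <- vapply(episodes, function(e) as.integer(e[[2]]), integer(1))
  if (anyNA(stim) || any(stim < 1L)) stop("stimulus ids must be positive integers")
  if (anyNA(reps) || any(reps < 1L))
    stop("episode repetition counts must be >= 1")
  if (is.null(n_stimuli)) n_stimuli <- max(stim)
  if (any(stim > n_stimuli)) stop("stimulus id exceeds 'n_stimuli'")
  labels <- rep(stim, times = reps)
  eps <- rep(seq_along(episodes) + as.integer(first_episode_id) - 1L,
             times = reps)
  new_schedule(labels, eps, n_stimuli = as.integer(n_stimuli))
}

#' Concatenate schedules
#'
#' @param ... `stim_schedule` objects, typically a training schedule followed
#'   by a testing schedule. Episode ids must be non-decreasing across the
#'   concatenation.
#' @return a `stim_schedule`
#' @export
concat_schedules <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "stim_schedule")))
  labels <- unlist(lapply(parts, `[[`, "stimulus"))
  eps <- unlist(lapply(parts, `[[`, "episode"))
  if (is.unsorted(eps)) stop("episode ids must be non-decreasing")
  new_schedule(labels, eps,
               n_stimuli = max(vapply(parts, attr, integer(1), "n_stimuli")))
}

new_schedule <- function(stimulus, episode, n_stimuli) {
  sch <- data.frame(stimulus = as.integer(stimulus),
                    episode = as.integer(episode))
  attr(sch, "n_stimuli") <- as.integer(n_stimuli)
  class(sch) <- c("stim_schedule", "data.frame")
  sch
}

#' Default schedules of the benchmark
#'
#' The default training schedule presents five stimuli 40, 50, 20, 20 and 20
#' times (150 samples) in a seeded random interleaving. The default testing
#' schedule presents the stimuli in 14 fixed episodes of repeated applications
#' (episode lengths between 1 and 201, irregularly ordered), totalling 25, 60,
#' 75, 188 and 358 presentations per stimulus (706 samples).
#'
#' @param seed seed for the training-phase interleaving.
#' @return a `stim_schedule`
#' @export
default_training_schedule <- function(seed = 1L) {
  make_training_schedule(c(40L, 50L, 20L, 20L, 20L), seed = seed)
}

#' @rdname default_training_schedule
#' @export
default_testing_schedule <- function() {
  eps <- list(
    c(3, 40), c(1, 12), c(4, 100), c(2, 20), c(5, 201), c(4, 58), c(2, 25),
    c(5, 100), c(1, 13), c(3, 35), c(5, 1), c(4, 30), c(2, 15), c(5, 56)
  )
  make_testing_schedule(eps, first_episode_id = 1L, n_stimuli = 5L)
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: %d presentations of %d stimuli, %d episode(s)\n",
              nrow(x), attr(x, "n_stimuli"),
              length(unique(x$episode))))
  tal <- tabulate(x$stimulus, nbins = attr(x, "n_stimuli"))
  cat("per-stimulus counts:", paste(tal, collapse = ", "), "\n")
  invisible(x)
}
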