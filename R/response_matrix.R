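#' Sensor-array response tables
#'
#' A `response_matrix` holds the time-ordered output of a multichannel gas
#' sensor array: one row per stimulus exposure, one column per sensor channel.
#' Values are normalised response amplitudes (dimensionless, in `[0, 1]` for
#' simulated or normalised data). Row metadata carries the stimulus label, the
#' episode id and a strictly increasing sample index; column metadata carries
#' the sensor-class membership of each channel.
#'
#' @param values numeric matrix, samples x channels, finite.
#' @param stimulus integer vector of per-sample stimulus labels.
#' @param episode integer vector of per-sample episode ids.
#' @param channel_class integer vector: sensor class of each channel.
#' @param sample_index strictly increasing integer vector (default `1:n`).
#' @return an object of class `response_matrix`
#' @export
response_matrix <- function(values, stimulus, episode,
                            channel_class, sample_index = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_index)) sample_index <- seq_len(n)
  stimulus <- as.integer(stimulus); episode <- as.integer(episode)
  channel_class <- as.integer(channel_class)
  sample_index <- as.integer(sample_index)
  if (length(stimulus) != n || length(episode) != n || length(sample_index) != n)
    stop("row metadata length must equal nrow(values)")
  if (length(channel_class) != ncol(values))
    stop("'channel_class' length must equal ncol(values)")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (n > 1 && any(diff(sample_index) <= 0))
    stop("'sample_index' must be strictly increasing")
  colnames(values) <- sprintf("ch%02d", seq_len(ncol(values)))
  structure(list(values = values, stimulus = stimulus, episode = episode,
                 channel_class = channel_class, sample_index = sample_index),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d samples x %d channels (%d sensor classes, %d stimuli)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$channel_class)), length(unique(x$stimulus))))
  cat(sprintf("sample_index %d..%d, episodes %d..%d\n",
              min(x$sample_index), max(x$sample_index),
              min(x$episode), max(x$episode)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Subset a response matrix by row
#'
#' @param data a `response_matrix`
#' @param rows logical or integer row index
#' @return a `response_matrix` with the selected samples
#' @export
subset_samples <- function(data, rows) {
  stopifnot(inherits(data, "response_matrix"))
  response_matrix(data$values[rows, , drop = FALSE], data$stimulus[rows],
                  data$episode[rows], data$channel_class,
                  data$sample_index[rows])
}

#' Channel-channel Pearson correlation of a response table
#'
#' Returns the Pearson correlation matrix of the channel columns, as used to
#' characterise correlated drift across sensors of the same and of different
#' classes. Channels with zero variance yield `NA` correlations (with a
#' warning), since correlation is undefined for a constant signal.
#'
#' @param data a `response_matrix` with at least two samples
#' @return channels x channels symmetric correlation matrix with unit diagonal
#' @export
correlation_matrix <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  v <- data$values
  if (nrow(v) < 2) stop("need at least 2 samples")
  sds <- apply(v, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(v))
  if (any(sds == 0)) {
    warning("constant channel(s): ", paste(which(sds == 0), collapse = ", "),
            "; correlations reported as NA")
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
  }
  diag(cm) <- ifelse(sds == 0, NA_real_, 1)
  cm
}
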