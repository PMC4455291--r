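#' Robust per-channel normalisation to [0, 1]
#'
#' Maps raw response amplitudes channel-wise into the unit interval using the
#' 1% and 99% percentiles of the *training* data as robust range estimates
#' (immune to occasional spikes), then clips to `[0, 1]`. The robust range is
#' mapped onto the interior target interval `range` (default `[0.1, 0.9]`)
#' rather than onto `[0, 1]` itself: on the network's input scale, `r = 0`
#' denotes a *dead* sensor (the dropout fault state), so the weakest healthy
#' response of a channel must remain strictly positive — pinning it at 0 would
#' make the adaptive weights of that channel decay as if the sensor had failed
#' whenever its stimulus is applied for a long episode. The fitted statistics
#' are applied unchanged to later data, so a test stream is normalised exactly
#' as the training stream was. A constant training channel gets a unit-scale
#' fallback (offset only) with a warning.
#'
#' @param train a `response_matrix` of training samples
#' @param probs length-2 probabilities of the robust range (default 1%/99%)
#' @param range length-2 target interval the robust range is mapped onto
#' @return object of class `normalizer` with per-channel `lo` and `hi` and the
#'   target `range`
#' @export
normalize_fit <- function(train, probs = c(0.01, 0.99), range = c(0.1, 0.9)) {
  stopifnot(inherits(train, "response_matrix"))
  v <- train$values
  if (nrow(v) == 0) stop("'train' must be non-empty")
  lo <- apply(v, 2, stats::quantile, probs = probs[1], names = FALSE)
  hi <- apply(v, 2, stats::quantile, probs = probs[2], names = FALSE)
  flat <- hi <= lo
  if (any(flat)) {
    warning("constant channel(s) ", paste(which(flat), collapse = ", "),
            ": unit-scale fallback")
    hi[flat] <- lo[flat] + 1
  }
  if (length(range) != 2 || range[1] < 0 || range[2] > 1 || range[1] >= range[2])
    stop("'range' must be an increasing interval inside [0, 1]")
  structure(list(lo = lo, hi = hi, range = range), class = "normalizer")
}

#' @rdname normalize_fit
#' @param stats a fitted `normalizer`
#' @param data a `response_matrix` to normalise
#' @export
normalize_apply <- function(stats, data) {
  stopifnot(inherits(stats, "normalizer"), inherits(data, "response_matrix"))
  if (ncol(data$values) != length(stats$lo))
    stop("channel count does not match the fitted normalizer")
  v <- sweep(sweep(data$values, 2, stats$lo), 2, stats$hi - stats$lo, `/`)
  rg <- if (is.null(stats$range)) c(0, 1) else stats$range
  v <- rg[1] + (rg[2] - rg[1]) * v
  out <- data
  out$values <- pmin(pmax(v, 0), 1)
  out
}
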