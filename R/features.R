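# Windowed-means feature extraction: baseline correction, per-window channel
# means over 150-700 ms in 50 ms steps, channel-major concatenation (11
# windows x 19 channels = 209 features at the study defaults), unit-norm rows.

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean of the pre-stimulus window from
#' the whole trial; the pre-stimulus mean of the output is 0 to numerical
#' precision.
#'
#' @param epochs An `erp_epochs` whose `t0_offset` covers at least
#'   `baseline_ms`.
#' @param baseline_ms Length of the pre-stimulus baseline window in ms.
#' @return The corrected `erp_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_ms = 500) {
  stopifnot(inherits(epochs, "erp_epochs"))
  nb <- round(baseline_ms * epochs$sampling_rate / 1000)
  if (nb < 1 || nb > epochs$t0_offset) {
    stop(sprintf("baseline window (%d samples) exceeds the pre-stimulus span (%d samples)",
                 nb, epochs$t0_offset), call. = FALSE)
  }
  d <- epochs$data
  # per trial x channel mean over the last nb pre-stimulus samples
  pre <- d[, , (epochs$t0_offset - nb + 1L):epochs$t0_offset, drop = FALSE]
  base <- apply(pre, c(1, 2), mean)
  out <- d - array(rep(base, dim(d)[3]), dim(d))
  epochs$data <- out
  epochs
}

#' Windowed-means features
#'
#' For each channel and each half-open post-stimulus window
#' `[w, w + width_ms)` ms, takes the mean of the contained samples. Features
#' are concatenated channel-major (all windows of channel 1, then channel 2,
#' ...); the defaults give 11 windows per channel and, with 19 channels, 209
#' features. Window boundaries map to sample indices by `floor(t*fs/1000)`.
#'
#' @param epochs An `erp_epochs` (typically baseline-corrected first).
#' @param start_ms,end_ms Post-stimulus span covered by the windows.
#' @param width_ms Window width; must divide `end_ms - start_ms`.
#' @return An unnormalized `erp_features`.
#' @export
windowed_means <- function(epochs, start_ms = 150, end_ms = 700, width_ms = 50) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (width_ms <= 0 || end_ms <= start_ms) {
    stop("window parameters must satisfy width_ms > 0 and end_ms > start_ms",
         call. = FALSE)
  }
  span <- end_ms - start_ms
  if (abs(span %% width_ms) > 1e-9) {
    stop("(end_ms - start_ms) must be divisible by width_ms", call. = FALSE)
  }
  fs <- epochs$sampling_rate
  d <- dim(epochs$data)
  n_windows <- as.integer(round(span / width_ms))
  starts <- start_ms + (seq_len(n_windows) - 1) * width_ms
  last_sample <- epochs$t0_offset + floor(end_ms * fs / 1000)
  if (last_sample > d[3]) {
    stop("windows exceed the post-stimulus span of the epochs", call. = FALSE)
  }

  ch_labels <- epochs$channel_labels %||% paste0("Ch", seq_len(d[2]))
  values <- matrix(0, d[1], d[2] * n_windows)
  feature_names <- character(d[2] * n_windows)
  col <- 0L
  for (ch in seq_len(d[2])) {
    for (w in seq_len(n_windows)) {
      col <- col + 1L
      a <- epochs$t0_offset + floor(starts[w] * fs / 1000) + 1L
      b <- epochs$t0_offset + floor((starts[w] + width_ms) * fs / 1000)
      values[, col] <- rowMeans(epochs$data[, ch, a:b, drop = FALSE], dims = 1)
      feature_names[col] <- sprintf("%s:%g", ch_labels[ch], starts[w])
    }
  }
  new_features(values, epochs$labels, feature_names,
               subject_ids = epochs$trial_subjects %||%
                 rep(epochs$subject_id, d[1]))
}

#' Scale each feature vector to unit Euclidean norm
#'
#' @param features An `erp_features` with no all-zero row.
#' @return The normalized `erp_features` (each row has norm 1).
#' @export
normalize_rows <- function(features) {
  stopifnot(inherits(features, "erp_features"))
  norms <- sqrt(rowSums(features$values^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop(sprintf("cannot normalize all-zero feature row(s): trial %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  features$values <- features$values / norms
  attr(features, "normalized") <- TRUE
  features
}
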