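# Core data containers: continuous recordings, epoch sets, feature matrices.
# Plain lists with S3 classes; marker onsets are 0-based sample indices so
# window arithmetic matches the usual EEG convention (onset k, 1 kHz, window
# [-500, +1000) ms -> samples [k-500, k+1000)).

#' Construct a continuous multi-channel recording
#'
#' @param signal Numeric matrix, channels x samples, in uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param markers Data frame with columns `onset_sample` (0-based) and
#'   `code` (marker string); may have zero rows.
#' @param metadata Free-form list (subject id, phase boundaries, seeds, ...).
#' @return An `erp_recording`.
#' @export
new_recording <- function(signal, sampling_rate, channel_labels,
                          markers = data.frame(onset_sample = integer(0),
                                               code = character(0)),
                          metadata = list()) {
  if (!is.matrix(signal) || nrow(signal) < 1L || ncol(signal) < 1L) {
    stop("`signal` must be a channels x samples matrix with >= 1 channel and sample",
         call. = FALSE)
  }
  if (length(channel_labels) != nrow(signal)) {
    stop("`channel_labels` length must equal the channel count", call. = FALSE)
  }
  if (nrow(markers) > 0 &&
      (any(markers$onset_sample < 0) || any(markers$onset_sample >= ncol(signal)))) {
    stop("marker onsets must lie within [0, n_samples)", call. = FALSE)
  }
  structure(list(signal = signal,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_labels = as.character(channel_labels),
                 markers = markers,
                 metadata = metadata),
            class = "erp_recording")
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate, nrow(x$markers)))
  if (!is.null(x$metadata$subject_id)) {
    cat(sprintf("  subject: %s\n", x$metadata$subject_id))
  }
  tab <- table(normalize_code(x$markers$code))
  if (length(tab)) {
    cat("  marker counts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an epoch set
#'
#' @param data Numeric array, trials x channels x samples, in uV.
#' @param labels Factor (or character) of per-trial classes with levels
#'   `nontarget`, `target`.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0_offset Samples from epoch start to stimulus onset (at 1 kHz with
#'   the default window: 500).
#' @param subject_id Subject identifier.
#' @param onsets Optional 0-based marker onsets, one per trial, used for
#'   chronological selections.
#' @return An `erp_epochs` object.
#' @export
new_epochs <- function(data, labels, sampling_rate, t0_offset,
                       subject_id = NA_character_, onsets = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a trials x channels x samples array", call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = c("nontarget", "target"))
  if (length(labels) != dim(data)[1]) {
    stop("`labels` length must equal the trial count", call. = FALSE)
  }
  structure(list(data = data, labels = labels,
                 sampling_rate = as.numeric(sampling_rate),
                 t0_offset = as.integer(t0_offset),
                 subject_id = as.character(subject_id),
                 onsets = if (is.null(onsets)) rep(NA_integer_, length(labels))
                          else as.integer(onsets)),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<erp_epochs> %d trials x %d channels x %d samples @ %g Hz (t0 at sample %d)\n",
              d[1], d[2], d[3], x$sampling_rate, x$t0_offset))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = ", "),
      sprintf(" subject: %s\n", x$subject_id))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `erp_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

# subset trials of an epoch set, preserving metadata
epochs_subset <- function(x, idx) {
  new_epochs(x$data[idx, , , drop = FALSE], x$labels[idx], x$sampling_rate,
             x$t0_offset, x$subject_id, x$onsets[idx])
}

# stack epoch sets along the trial axis (dimensions must agree)
epochs_bind <- function(sets) {
  d <- dim(sets[[1]]$data)
  for (s in sets) {
    if (!all(dim(s$data)[2:3] == d[2:3]) ||
        s$t0_offset != sets[[1]]$t0_offset ||
        s$sampling_rate != sets[[1]]$sampling_rate) {
      stop("epoch sets are not dimensionally compatible", call. = FALSE)
    }
  }
  n_tot <- sum(vapply(sets, n_trials, integer(1)))
  out <- array(0, c(n_tot, d[2], d[3]))
  labels <- character(n_tot)
  onsets <- integer(n_tot)
  subj <- character(n_tot)
  at <- 0L
  for (s in sets) {
    k <- n_trials(s)
    out[at + seq_len(k), , ] <- s$data
    labels[at + seq_len(k)] <- as.character(s$labels)
    onsets[at + seq_len(k)] <- s$onsets
    subj[at + seq_len(k)] <- s$subject_id
    at <- at + k
  }
  es <- new_epochs(out, labels, sets[[1]]$sampling_rate, sets[[1]]$t0_offset,
                   subject_id = "pooled", onsets = onsets)
  es$trial_subjects <- subj
  es
}

#' Construct a feature matrix
#'
#' @param values Numeric matrix, trials x features.
#' @param labels Per-trial class factor (`nontarget`/`target`).
#' @param feature_names Ordered "channel:window-start-ms" descriptors.
#' @param subject_ids Optional per-trial subject ids.
#' @return An `erp_features` object.
#' @export
new_features <- function(values, labels, feature_names,
                         subject_ids = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("nontarget", "target"))
  if (length(labels) != nrow(values)) {
    stop("`labels` length must equal the row count", call. = FALSE)
  }
  if (length(feature_names) != ncol(values)) {
    stop("`feature_names` length must equal the column count", call. = FALSE)
  }
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = as.character(feature_names),
                 subject_ids = subject_ids),
            class = "erp_features")
}

#' @export
print.erp_features <- function(x, ...) {
  cat(sprintf("<erp_features> %d trials x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

# internal single-file container (R native serialization + format sentinel) --

CONTAINER_SENTINEL <- "p300sae-container-v1"

#' Write a recording (or any package container) to a single file
#'
#' @param x An `erp_recording`, `erp_epochs` or `erp_features` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  if (!inherits(x, c("erp_recording", "erp_epochs", "erp_features"))) {
    stop("`x` must be a package container object", call. = FALSE)
  }
  saveRDS(list(sentinel = CONTAINER_SENTINEL, payload = x), path)
  invisible(path)
}

#' Read a container file written by [write_container()]
#'
#' @param path File path.
#' @return The stored object, bit-identical to what was written.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("'%s' is not a readable container file (%s)",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$sentinel, CONTAINER_SENTINEL)) {
    stop(sprintf("'%s' is not a p300sae container file", path), call. = FALSE)
  }
  obj$payload
}
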