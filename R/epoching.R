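# Marker-locked epoch extraction and trial-set assembly for the
# multi-subject train/test design: pooled balanced training set (all targets
# + per-subject random non-target subset), chronological balanced test sets.

#' Cut marker-locked epochs from a continuous recording
#'
#' One trial per target/non-target marker, spanning the half-open window
#' `[-pre_ms, +post_ms)` around stimulus onset (1500 samples at 1 kHz with
#' the defaults). Trials whose window overruns either edge of the recording
#' are dropped with a logged count; markers with other codes (distractors)
#' are ignored. Codes are matched after whitespace normalization.
#'
#' @param recording An `erp_recording`.
#' @param target_code,nontarget_code Marker strings labelling the two classes.
#' @param pre_ms Pre-stimulus span in ms (> 0).
#' @param post_ms Post-stimulus span in ms (> 0).
#' @return An `erp_epochs`; attribute `n_dropped` counts edge-dropped trials.
#' @export
extract_epochs <- function(recording, target_code = "S  2",
                           nontarget_code = "S  4",
                           pre_ms = 500, post_ms = 1000) {
  stopifnot(inherits(recording, "erp_recording"))
  if (pre_ms <= 0 || post_ms <= 0) {
    stop("`pre_ms` and `post_ms` must be positive", call. = FALSE)
  }
  fs <- recording$sampling_rate
  pre <- round(pre_ms * fs / 1000)
  post <- round(post_ms * fs / 1000)
  len <- pre + post
  n_samples <- ncol(recording$signal)

  codes <- normalize_code(recording$markers$code)
  tc <- normalize_code(target_code)
  nc <- normalize_code(nontarget_code)
  keep <- codes %in% c(tc, nc)
  if (!any(keep)) {
    warning("no target or non-target markers found; returning empty epoch set")
  }
  onsets <- recording$markers$onset_sample[keep]
  labels <- ifelse(codes[keep] == tc, "target", "nontarget")

  # half-open window [onset - pre, onset + post) in 0-based samples
  inside <- (onsets - pre) >= 0 & (onsets + post) <= n_samples
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    message(sprintf("extract_epochs: dropped %d trial(s) overrunning the recording edge",
                    n_dropped))
  }
  onsets <- onsets[inside]
  labels <- labels[inside]

  n <- length(onsets)
  data <- array(0, c(n, nrow(recording$signal), len))
  for (i in seq_len(n)) {
    idx <- (onsets[i] - pre + 1L):(onsets[i] + post)  # 1-based slice
    data[i, , ] <- recording$signal[, idx]
  }
  es <- new_epochs(data, labels, fs, t0_offset = pre,
                   subject_id = recording$metadata$subject_id %||% NA_character_,
                   onsets = onsets)
  es$channel_labels <- recording$channel_labels
  attr(es, "n_dropped") <- n_dropped
  es
}

#' Assemble the pooled balanced training set
#'
#' Per subject, keeps all target trials plus an equal-count uniform random
#' subset of that subject's non-targets, then shuffles the pooled trials.
#' The result is exactly class-balanced.
#'
#' @param epoch_sets Non-empty list of `erp_epochs`, one per training subject.
#' @param seed Integer seed driving both the non-target subsetting and the
#'   final shuffle.
#' @return A pooled `erp_epochs` with a `trial_subjects` field.
#' @export
assemble_training_set <- function(epoch_sets, seed) {
  if (length(epoch_sets) < 1L) {
    stop("`epoch_sets` must contain at least one subject", call. = FALSE)
  }
  parts <- vector("list", length(epoch_sets))
  for (i in seq_along(epoch_sets)) {
    es <- epoch_sets[[i]]
    tgt <- which(es$labels == "target")
    non <- which(es$labels == "nontarget")
    if (length(non) < length(tgt)) {
      stop(sprintf("subject %s has %d non-target trials for %d targets; cannot balance",
                   es$subject_id, length(non), length(tgt)), call. = FALSE)
    }
    pick <- with_seed(derive_seed(seed, i),
                      sort(sample(non, length(tgt), replace = FALSE)))
    parts[[i]] <- epochs_subset(es, sort(c(tgt, pick)))
  }
  pooled <- epochs_bind(parts)
  perm <- with_seed(derive_seed(seed, 0), sample.int(n_trials(pooled)))
  out <- epochs_subset(pooled, perm)
  out$trial_subjects <- pooled$trial_subjects[perm]
  out$subject_id <- "pooled"
  out
}

#' Balanced per-subject test-trial selection
#'
#' Keeps all target trials plus the chronologically first equal number of
#' non-target trials; the original trial order is preserved.
#'
#' @param epoch_set An `erp_epochs` for one subject.
#' @return A balanced `erp_epochs`.
#' @export
select_test_trials <- function(epoch_set) {
  stopifnot(inherits(epoch_set, "erp_epochs"))
  tgt <- which(epoch_set$labels == "target")
  non <- which(epoch_set$labels == "nontarget")
  if (length(non) < length(tgt)) {
    stop(sprintf("subject %s has %d non-target trials for %d targets; cannot balance",
                 epoch_set$subject_id, length(non), length(tgt)), call. = FALSE)
  }
  ord <- non[order(epoch_set$onsets[non])]
  keep <- sort(c(tgt, ord[seq_along(tgt)]))
  epochs_subset(epoch_set, keep)
}

#' Split a feature matrix into training and validation parts
#'
#' Disjoint random partition with the validation size rounded to the nearest
#' integer (`732` rows at fraction `0.2` gives `586/146`).
#'
#' @param features An `erp_features`.
#' @param fraction Validation fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation` (both `erp_features`).
#' @export
split_validation <- function(features, fraction = 0.2, seed) {
  stopifnot(inherits(features, "erp_features"))
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(features$values)
  n_val <- round(fraction * n)
  if (n_val < 1 || n_val >= n) {
    stop("split is degenerate: one part would be empty", call. = FALSE)
  }
  val_idx <- with_seed(seed, sort(sample.int(n, n_val)))
  train_idx <- setdiff(seq_len(n), val_idx)
  list(train = features_subset(features, train_idx),
       validation = features_subset(features, val_idx))
}

features_subset <- function(fm, idx) {
  new_features(fm$values[idx, , drop = FALSE], fm$labels[idx],
               fm$feature_names,
               subject_ids = if (is.null(fm$subject_ids)) NULL else fm$subject_ids[idx])
}
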