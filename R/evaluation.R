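# Evaluation layer: confusion counts with target as the positive class,
# accuracy/precision/recall in percent, McNemar paired comparison, and the
# full multi-subject study driver.

#' Confusion counts for binary single-trial detection
#'
#' The target class (P300 present) is the positive class.
#'
#' @param truth,predicted Equal-length factors/characters with values in
#'   `nontarget`/`target`.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  ok <- c("nontarget", "target")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'target' or 'nontarget'", call. = FALSE)
  }
  structure(list(
    tp = sum(truth == "target" & predicted == "target"),
    tn = sum(truth == "nontarget" & predicted == "nontarget"),
    fp = sum(truth == "nontarget" & predicted == "target"),
    fn = sum(truth == "target" & predicted == "nontarget")
  ), class = "confusion_counts")
}

#' Accuracy, precision and recall in percent
#'
#' Accuracy = (tp+tn)/(tp+tn+fp+fn), precision = tp/(tp+fp),
#' recall = tp/(tp+fn), each multiplied by 100. A metric with a zero
#' denominator is reported as `NA` with a warning.
#'
#' @param counts A `confusion_counts` (or list with tp/tn/fp/fn).
#' @return Named numeric vector `c(accuracy, precision, recall)` in percent.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    warning("precision undefined (tp + fp = 0); reporting NA"); NA_real_
  }
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("recall undefined (tp + fn = 0); reporting NA"); NA_real_
  }
  c(accuracy = 100 * (tp + tn) / total, precision = prec, recall = rec)
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant trials (`b`: A correct / B wrong, `c`: A wrong / B
#' correct). With fewer than `exact_threshold` discordant pairs the exact
#' two-sided binomial test is used; otherwise the chi-square statistic with
#' continuity correction, `(|b-c|-1)^2/(b+c)` on 1 df. With no discordant
#' pairs the p-value is 1.
#'
#' @param preds_a,preds_b Predicted labels of the two classifiers.
#' @param truth True labels.
#' @param exact_threshold Discordant-pair count below which the exact
#'   binomial branch is used (default 25).
#' @return List with `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_compare <- function(preds_a, preds_b, truth, exact_threshold = 25) {
  preds_a <- as.character(preds_a); preds_b <- as.character(preds_b)
  truth <- as.character(truth)
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth)) {
    stop("prediction and truth vectors must have equal length", call. = FALSE)
  }
  a_ok <- preds_a == truth
  b_ok <- preds_b == truth
  b <- sum(a_ok & !b_ok)
  cc <- sum(!a_ok & b_ok)
  n <- b + cc
  if (n == 0) {
    return(list(b = b, c = cc, p_value = 1, method = "degenerate (no discordant pairs)"))
  }
  if (n < exact_threshold) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  list(b = b, c = cc, p_value = p, method = method)
}

#' Run the full simulated study
#'
#' End-to-end pipeline at the study design: simulate (or load) one session
#' per subject, epoch around the target/non-target markers, extract
#' baseline-corrected windowed-means features with unit-norm rows, assemble
#' the pooled balanced training set from the training subjects, train the
#' requested classifiers, and evaluate each on every test subject's balanced
#' chronological test set. No parameters are updated during testing.
#'
#' @param config A `study_config` (see [study_config()] /
#'   [read_study_config()]).
#' @return A `metrics_report` with per-subject metrics, per-classifier
#'   averages, and pooled pairwise McNemar comparisons.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  train_ids <- vapply(config$profiles_train, function(p) p$subject_id, character(1))
  test_ids <- vapply(config$profiles_test, function(p) p$subject_id, character(1))
  if (length(intersect(train_ids, test_ids))) {
    stop("training and testing subject lists must be disjoint", call. = FALSE)
  }
  seed <- config$seed
  fp <- config$feature_params
  sim <- config$sim

  featurize <- function(epochs) {
    normalize_rows(windowed_means(baseline_correct(epochs, fp$baseline_ms),
                                  fp$start_ms, fp$end_ms, fp$width_ms))
  }
  get_epochs <- function(i, profile) {
    rec <- if (!is.null(config$recording_files)) {
      load_recording(config$recording_files[[profile$subject_id]])
    } else {
      simulate_session(sim, profile, cohort_subject_seed(seed, i))
    }
    extract_epochs(rec, sim$target_code, sim$nontarget_code,
                   fp$pre_ms, fp$post_ms)
  }

  # training set: subjects occupy cohort positions 1..n_train
  train_sets <- lapply(seq_along(config$profiles_train), function(i) {
    get_epochs(i, config$profiles_train[[i]])
  })
  train_epochs <- assemble_training_set(train_sets, derive_seed(seed, 5))
  rm(train_sets)
  fm_train <- featurize(train_epochs)

  models <- list()
  if ("sae" %in% config$models) {
    models$sae <- train_sae(fm_train, config$sae_hyper, derive_seed(seed, 6))
  }
  if ("mlp" %in% config$models) {
    models$mlp <- train_mlp(fm_train, config$sae_hyper$layer_sizes,
                            config$mlp_iterations, derive_seed(seed, 7))
  }
  if ("lda" %in% config$models) {
    models$lda <- train_shrinkage_lda(fm_train)
  }
  if (!length(models)) stop("no classifiers requested in `models`", call. = FALSE)

  per_subject <- list()
  pooled <- list(truth = character(0))
  for (m in names(models)) pooled[[m]] <- character(0)

  n_train <- length(config$profiles_train)
  for (j in seq_along(config$profiles_test)) {
    prof <- config$profiles_test[[j]]
    es <- select_test_trials(get_epochs(n_train + j, prof))
    fm <- featurize(es)
    pooled$truth <- c(pooled$truth, as.character(fm$labels))
    for (m in names(models)) {
      pred <- predict(models[[m]], fm)$class
      pooled[[m]] <- c(pooled[[m]], as.character(pred))
      cts <- confusion(fm$labels, pred)
      mt <- metrics(cts)
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = prof$subject_id, classifier = m, n_trials = n_trials(es),
        tp = cts$tp, tn = cts$tn, fp = cts$fp, fn = cts$fn,
        accuracy = mt[["accuracy"]], precision = mt[["precision"]],
        recall = mt[["recall"]], stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, per_subject)

  averages <- do.call(rbind, lapply(names(models), function(m) {
    rows <- per_subject[per_subject$classifier == m, ]
    data.frame(classifier = m,
               accuracy = mean(rows$accuracy),
               precision = mean(rows$precision, na.rm = TRUE),
               recall = mean(rows$recall, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  mc <- NULL
  if (length(models) >= 2) {
    prs <- utils::combn(names(models), 2, simplify = FALSE)
    mc <- do.call(rbind, lapply(prs, function(pr) {
      r <- mcnemar_compare(pooled[[pr[1]]], pooled[[pr[2]]], pooled$truth,
                           config$mcnemar_exact_threshold)
      data.frame(classifier_a = pr[1], classifier_b = pr[2],
                 b = r$b, c = r$c, p_value = r$p_value, method = r$method,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(per_subject = per_subject, averages = averages,
                 mcnemar = mc, pooled_predictions = pooled,
                 models = names(models),
                 seed = seed, n_train_trials = n_trials(train_epochs)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d test subject(s), %d training trials, seed %s\n",
              length(unique(x$per_subject$subject)), x$n_train_trials, x$seed))
  cat("\nAverage classification performance:\n")
  av <- x$averages
  av$accuracy <- sprintf("%.1f", av$accuracy)
  av$precision <- sprintf("%.1f", av$precision)
  av$recall <- sprintf("%.1f", av$recall)
  print(av, row.names = FALSE)
  if (!is.null(x$mcnemar)) {
    cat("\nMcNemar paired comparisons (pooled test trials):\n")
    mc <- x$mcnemar
    mc$p_value <- signif(mc$p_value, 3)
    print(mc[, c("classifier_a", "classifier_b", "b", "c", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}

# load a recording from a BrainVision header or a container file
load_recording <- function(path) {
  if (grepl("\\.vhdr$", path, ignore.case = TRUE)) read_brainvision(path)
  else read_container(path)
}
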