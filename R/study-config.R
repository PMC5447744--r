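# Study configuration: one structured (YAML) file drives the whole pipeline
# so every empirically tuned constant is auditable in one place. A saved
# config re-run with the same master seed reproduces the report bit-for-bit.

#' Build a study configuration
#'
#' @param sim A [sim_config()] shared by all subjects.
#' @param profiles_train,profiles_test Disjoint lists of
#'   [subject_profile()]s; training subjects occupy cohort seed positions
#'   `1..n_train`, test subjects follow.
#' @param feature_params List with `pre_ms`, `post_ms`, `baseline_ms`,
#'   `start_ms`, `end_ms`, `width_ms`.
#' @param sae_hyper An [sae_hyperparams()].
#' @param mlp_iterations Backpropagation iterations for the MLP baseline.
#' @param models Character subset of `c("sae", "mlp", "lda")`.
#' @param seed Master integer seed.
#' @param mcnemar_exact_threshold Discordant-pair switch point of
#'   [mcnemar_compare()].
#' @param recording_files Optional named list (subject id -> path to a
#'   `.vhdr` or container file) replacing simulation with file input.
#' @return A `study_config`.
#' @export
study_config <- function(sim = sim_config(),
                         profiles_train, profiles_test,
                         feature_params = list(pre_ms = 500, post_ms = 1000,
                                               baseline_ms = 500, start_ms = 150,
                                               end_ms = 700, width_ms = 50),
                         sae_hyper = sae_hyperparams(),
                         mlp_iterations = 1000,
                         models = c("sae", "mlp", "lda"),
                         seed = 1,
                         mcnemar_exact_threshold = 25,
                         recording_files = NULL) {
  cfg <- list(sim = sim, profiles_train = profiles_train,
              profiles_test = profiles_test,
              feature_params = feature_params,
              sae_hyper = sae_hyper,
              mlp_iterations = check_count(mlp_iterations, "mlp_iterations"),
              models = match.arg(models, c("sae", "mlp", "lda"), several.ok = TRUE),
              seed = check_count(seed, "seed"),
              mcnemar_exact_threshold = check_count(mcnemar_exact_threshold,
                                                    "mcnemar_exact_threshold"),
              recording_files = recording_files)
  structure(cfg, class = "study_config")
}

#' Cohort profiles with subject-to-subject response variability
#'
#' Convenience generator for simulated cohorts: P300 amplitudes drawn
#' uniformly from `amplitude_range` (conventional single-subject peak
#' amplitudes), latencies from `latency_range`, fixed jitter and width.
#'
#' @param n Number of subjects.
#' @param seed Integer seed for the parameter draws.
#' @param amplitude_range Min/max peak amplitude in uV.
#' @param latency_range Min/max mean latency in ms.
#' @param latency_jitter_sd Trial-to-trial latency jitter SD in ms.
#' @param p300_width Temporal spread (Gaussian SD) in ms.
#' @param id_prefix Prefix of the generated subject ids.
#' @param n_channels Channel count.
#' @return List of [subject_profile()]s.
#' @export
make_cohort_profiles <- function(n, seed, amplitude_range = c(2, 10),
                                 latency_range = c(350, 450),
                                 latency_jitter_sd = 30, p300_width = 60,
                                 id_prefix = "sim", n_channels = 19) {
  n <- check_count(n, "n")
  amps <- with_seed(derive_seed(seed, 81),
                    stats::runif(n, amplitude_range[1], amplitude_range[2]))
  lats <- with_seed(derive_seed(seed, 82),
                    stats::runif(n, latency_range[1], latency_range[2]))
  lapply(seq_len(n), function(i) {
    subject_profile(subject_id = sprintf("%s%02d", id_prefix, i),
                    p300_amplitude = amps[i], p300_latency = round(lats[i]),
                    latency_jitter_sd = latency_jitter_sd,
                    p300_width = p300_width, n_channels = n_channels)
  })
}

#' Read a study configuration from a YAML file
#'
#' The file mirrors the [study_config()] fields; subject profiles are given
#' as lists of [subject_profile()] arguments, the simulator settings as
#' [sim_config()] arguments (with `noise_model` as a nested mapping), and
#' hyperparameters as [sae_hyperparams()] arguments. Omitted fields fall
#' back to the package defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`; the source file's MD5 hash is attached as
#'   attribute `config_hash` for provenance logging.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)

  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$noise_model)) {
    sim_args$noise_model <- do.call(noise_model, sim_args$noise_model)
  }
  sim <- do.call(sim_config, sim_args)

  build_profiles <- function(entries) {
    lapply(entries, function(e) {
      e$n_channels <- e$n_channels %||% sim$n_channels
      do.call(subject_profile, e)
    })
  }
  profiles_train <- build_profiles(y$profiles_train)
  profiles_test <- build_profiles(y$profiles_test)

  hyper <- do.call(sae_hyperparams, y$sae_hyper %||% list())

  fp_default <- list(pre_ms = 500, post_ms = 1000, baseline_ms = 500,
                     start_ms = 150, end_ms = 700, width_ms = 50)
  fp <- utils::modifyList(fp_default, y$feature_params %||% list())

  cfg <- study_config(sim = sim, profiles_train = profiles_train,
                      profiles_test = profiles_test,
                      feature_params = fp, sae_hyper = hyper,
                      mlp_iterations = y$mlp_iterations %||% 1000,
                      models = y$models %||% c("sae", "mlp", "lda"),
                      seed = y$seed %||% 1,
                      mcnemar_exact_threshold = y$mcnemar_exact_threshold %||% 25,
                      recording_files = y$recording_files)
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}

#' Write a metrics report as delimited tables
#'
#' Writes `<prefix>_per_subject.csv`, `<prefix>_averages.csv`, and (when
#' present) `<prefix>_mcnemar.csv`, plus a plain-text provenance log with the
#' master seed and config hash.
#'
#' @param report A `metrics_report`.
#' @param prefix Output path prefix (directories are created).
#' @param config_hash Optional config hash recorded in the log.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, prefix, config_hash = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(per_subject = paste0(prefix, "_per_subject.csv"),
             averages = paste0(prefix, "_averages.csv"))
  utils::write.csv(report$per_subject, paths["per_subject"], row.names = FALSE)
  utils::write.csv(report$averages, paths["averages"], row.names = FALSE)
  if (!is.null(report$mcnemar)) {
    paths["mcnemar"] <- paste0(prefix, "_mcnemar.csv")
    utils::write.csv(report$mcnemar, paths["mcnemar"], row.names = FALSE)
  }
  log_path <- paste0(prefix, "_log.txt")
  writeLines(c(sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("master seed: %s", report$seed),
               sprintf("training trials: %d", report$n_train_trials),
               sprintf("classifiers: %s", paste(report$models, collapse = ", ")),
               sprintf("config hash: %s", config_hash %||% "(in-memory config)")),
             log_path)
  paths["log"] <- log_path
  invisible(paths)
}
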