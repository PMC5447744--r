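# Shared fixtures: small simulation configs, hand-built containers, and a
# central-finite-difference gradient checker used by the oracle tests.

small_sim <- function(targets_per_phase = 5, n_phases = 1, ...) {
  sim_config(n_phases = n_phases, targets_per_phase = targets_per_phase, ...)
}

quiet_noise <- function() noise_model(pink_sd = 0.5, alpha_amplitude = 0.5,
                                      white_sd = 0.5)

no_noise <- function() noise_model(pink_sd = 0, alpha_amplitude = 0, white_sd = 0)

# profile without latency jitter, for deterministic response tracks
steady_profile <- function(amplitude = 5, ...) {
  subject_profile(p300_amplitude = amplitude, latency_jitter_sd = 0, ...)
}

# zero-signal recording with hand-placed markers
flat_recording <- function(n_channels = 2, n_samples = 5000,
                           onsets = integer(0), codes = character(0),
                           sampling_rate = 1000) {
  new_recording(matrix(0, n_channels, n_samples), sampling_rate,
                paste0("Ch", seq_len(n_channels)),
                markers = data.frame(onset_sample = as.integer(onsets),
                                     code = codes, stringsAsFactors = FALSE))
}

# hand-built epoch set: data is trials x channels x samples
manual_epochs <- function(data, labels, t0_offset = 500, sampling_rate = 1000,
                          channel_labels = NULL) {
  es <- new_epochs(data, labels, sampling_rate, t0_offset, subject_id = "fix")
  es$channel_labels <- channel_labels %||% paste0("Ch", seq_len(dim(data)[2]))
  es
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite differences over a named list of parameter arrays;
# returns the maximum relative error against the analytic gradient
max_grad_rel_error <- function(par, cost_of, grad, eps = 1e-6) {
  worst <- 0
  for (nm in names(par)) {
    p <- par[[nm]]
    for (i in seq_along(p)) {
      pp <- par
      pp[[nm]][i] <- p[i] + eps
      cp <- cost_of(pp)
      pp[[nm]][i] <- p[i] - eps
      cm <- cost_of(pp)
      g_num <- (cp - cm) / (2 * eps)
      rel <- abs(g_num - grad[[nm]][i]) / max(abs(g_num), abs(grad[[nm]][i]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  worst
}

# separable two-class Gaussian feature set in d dimensions
toy_features <- function(n_per_class = 30, d = 5, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
             matrix(rnorm(n_per_class * d), n_per_class, d))
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] - sep / 2
  X[n_per_class + seq_len(n_per_class), 1] <-
    X[n_per_class + seq_len(n_per_class), 1] + sep / 2
  list(X = X, labels = factor(rep(c("nontarget", "target"), each = n_per_class),
                              levels = c("nontarget", "target")))
}
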