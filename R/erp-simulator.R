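# Synthetic oddball-paradigm EEG sessions: continuous multi-channel signal
# with stimulus markers and target-locked P300 responses superposed on
# pink + alpha + white background activity.

TEN_TWENTY_19 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                   "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                   "Fz", "Cz", "Pz")

#' Channel labels for a simulated montage
#'
#' For 19 channels the standard 10-20 montage labels are used; other channel
#' counts fall back to generic names.
#'
#' @param n_channels Number of channels.
#' @return Character vector of labels.
#' @export
channel_labels_1020 <- function(n_channels = 19) {
  n_channels <- check_count(n_channels, "n_channels")
  if (n_channels == 19L) TEN_TWENTY_19 else paste0("Ch", seq_len(n_channels))
}

#' Background-activity noise model
#'
#' Describes the three additive components of the simulated background EEG:
#' 1/f ("pink") noise, a sinusoidal alpha rhythm with random per-channel
#' phase, and white Gaussian noise. Amplitudes are in microvolts.
#'
#' @param pink_sd Standard deviation of the pink-noise component (uV).
#' @param pink_exponent Spectral exponent of the 1/f component (power decays
#'   as 1/f^exponent).
#' @param alpha_amplitude Peak amplitude of the alpha sinusoid (uV).
#' @param alpha_freq Alpha frequency (Hz).
#' @param white_sd Standard deviation of the white-noise component (uV).
#' @return A `noise_model` list.
#' @export
noise_model <- function(pink_sd = 4, pink_exponent = 1,
                        alpha_amplitude = 4, alpha_freq = 10,
                        white_sd = 2) {
  nm <- list(
    pink_sd = check_scalar(pink_sd, "pink_sd", lower = 0),
    pink_exponent = check_scalar(pink_exponent, "pink_exponent", lower = 0),
    alpha_amplitude = check_scalar(alpha_amplitude, "alpha_amplitude", lower = 0),
    alpha_freq = check_scalar(alpha_freq, "alpha_freq", lower = 0),
    white_sd = check_scalar(white_sd, "white_sd", lower = 0)
  )
  structure(nm, class = "noise_model")
}

#' Simulation configuration for an oddball session
#'
#' Encodes the stimulation protocol and recording parameters of the study
#' design being emulated: 19 channels sampled at 1 kHz, one flash per second
#' (500 ms flash duration), stimulus-type probabilities 83/13.5/3.5% for
#' non-target/target/distractor, and three phases of 30 target stimuli each.
#'
#' @param n_channels Number of EEG channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_interval Inter-stimulus onset interval in seconds.
#' @param stim_duration Flash duration in seconds (informational only).
#' @param p_nontarget,p_target,p_distractor Stimulus-type probabilities; must
#'   sum to 1.
#' @param n_phases Number of experimental phases per session.
#' @param targets_per_phase Target-stimulus quota per phase; a phase runs
#'   until its quota is reached.
#' @param noise_model Background model, see [noise_model()].
#' @param target_code,nontarget_code,distractor_code Marker strings written
#'   into the stimulus track.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_channels = 19, sampling_rate = 1000,
                       stim_interval = 1.0, stim_duration = 0.5,
                       p_nontarget = 0.83, p_target = 0.135,
                       p_distractor = 0.035,
                       n_phases = 3, targets_per_phase = 30,
                       noise_model = p300sae::noise_model(),
                       target_code = "S  2", nontarget_code = "S  4",
                       distractor_code = "S  8") {
  cfg <- list(
    n_channels = check_count(n_channels, "n_channels"),
    sampling_rate = check_scalar(sampling_rate, "sampling_rate", lower = 1e-9),
    stim_interval = check_scalar(stim_interval, "stim_interval", lower = 1e-9),
    stim_duration = check_scalar(stim_duration, "stim_duration", lower = 1e-9),
    p_nontarget = check_scalar(p_nontarget, "p_nontarget", lower = 0, upper = 1),
    p_target = check_scalar(p_target, "p_target", lower = 0, upper = 1),
    p_distractor = check_scalar(p_distractor, "p_distractor", lower = 0, upper = 1),
    n_phases = check_count(n_phases, "n_phases"),
    targets_per_phase = check_count(targets_per_phase, "targets_per_phase"),
    noise_model = noise_model,
    target_code = target_code,
    nontarget_code = nontarget_code,
    distractor_code = distractor_code
  )
  if (abs(cfg$p_nontarget + cfg$p_target + cfg$p_distractor - 1) > 1e-12) {
    stop("stimulus probabilities must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (!inherits(noise_model, "noise_model")) {
    stop("`noise_model` must be created by noise_model()", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default centro-parietal P300 scalp topography
#'
#' Per-channel gain vector with maximum 1 at Pz and a centro-parietal
#' emphasis, matching the classic scalp distribution of the P300 component.
#'
#' @param n_channels Number of channels (19 gives the named 10-20 gains).
#' @return Numeric gain vector in `[0, 1]` with max 1.
#' @export
default_topography <- function(n_channels = 19) {
  n_channels <- check_count(n_channels, "n_channels")
  if (n_channels == 19L) {
    gains <- c(Fp1 = 0.10, Fp2 = 0.10, F3 = 0.30, F4 = 0.30,
               C3 = 0.60, C4 = 0.60, P3 = 0.80, P4 = 0.80,
               O1 = 0.40, O2 = 0.40, F7 = 0.15, F8 = 0.15,
               T3 = 0.20, T4 = 0.20, T5 = 0.35, T6 = 0.35,
               Fz = 0.50, Cz = 0.85, Pz = 1.00)
    return(gains[TEN_TWENTY_19])
  }
  # generic fall-back: linear ramp peaking at the last channel
  g <- seq(0.1, 1, length.out = n_channels)
  stats::setNames(g, paste0("Ch", seq_len(n_channels)))
}

#' Frontal topography for the distractor-evoked P3a
#' @param n_channels Number of channels.
#' @return Numeric gain vector with max 1 (Fz for the 19-channel montage).
#' @export
frontal_topography <- function(n_channels = 19) {
  n_channels <- check_count(n_channels, "n_channels")
  if (n_channels == 19L) {
    gains <- c(Fp1 = 0.60, Fp2 = 0.60, F3 = 0.80, F4 = 0.80,
               C3 = 0.55, C4 = 0.55, P3 = 0.30, P4 = 0.30,
               O1 = 0.10, O2 = 0.10, F7 = 0.50, F8 = 0.50,
               T3 = 0.25, T4 = 0.25, T5 = 0.15, T6 = 0.15,
               Fz = 1.00, Cz = 0.70, Pz = 0.40)
    return(gains[TEN_TWENTY_19])
  }
  g <- seq(1, 0.1, length.out = n_channels)
  stats::setNames(g, paste0("Ch", seq_len(n_channels)))
}

#' Subject response profile
#'
#' Describes how one simulated subject responds to target stimuli: P300 peak
#' amplitude, mean latency, trial-to-trial latency jitter, temporal width
#' (Gaussian SD of the bump), and a scalp gain vector. An optional distractor
#' response describes an earlier, frontally distributed P3a.
#'
#' @param subject_id Identifier stored in downstream containers.
#' @param p300_amplitude Peak amplitude at the maximum-gain channel (uV).
#'   Conventional single-subject values lie in roughly 2-10 uV.
#' @param p300_latency Mean peak latency in ms post-stimulus.
#' @param latency_jitter_sd Trial-to-trial latency jitter SD in ms.
#' @param p300_width Temporal spread (Gaussian SD) in ms.
#' @param topography Per-channel gain vector in `[0,1]`, max entry 1.
#' @param distractor_response Optional list with fields `amplitude`,
#'   `latency`, `width`, `topography` describing a P3a; `NULL` disables it.
#' @param n_channels Channel count the topography must match.
#' @param response_span_ms Post-stimulus span over which the response kernel
#'   is evaluated; latency + 2*width must fit inside it.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "S01", p300_amplitude = 5,
                            p300_latency = 400, latency_jitter_sd = 30,
                            p300_width = 60,
                            topography = default_topography(n_channels),
                            distractor_response = NULL,
                            n_channels = 19, response_span_ms = 1000) {
  prof <- list(
    subject_id = as.character(subject_id),
    p300_amplitude = check_scalar(p300_amplitude, "p300_amplitude", lower = 0),
    p300_latency = check_scalar(p300_latency, "p300_latency", lower = 0),
    latency_jitter_sd = check_scalar(latency_jitter_sd, "latency_jitter_sd", lower = 0),
    p300_width = check_scalar(p300_width, "p300_width", lower = 1e-9),
    topography = as.numeric(topography),
    distractor_response = distractor_response,
    n_channels = check_count(n_channels, "n_channels"),
    response_span_ms = check_scalar(response_span_ms, "response_span_ms", lower = 1)
  )
  names(prof$topography) <- names(topography)
  if (length(prof$topography) != prof$n_channels) {
    stop("`topography` must have exactly n_channels entries", call. = FALSE)
  }
  if (abs(max(prof$topography) - 1) > 1e-9) {
    stop("`topography` max entry must equal 1", call. = FALSE)
  }
  if (any(prof$topography < 0 | prof$topography > 1)) {
    stop("`topography` entries must lie in [0, 1]", call. = FALSE)
  }
  if (prof$p300_latency + 2 * prof$p300_width > prof$response_span_ms) {
    stop("p300_latency + 2*p300_width must fit inside response_span_ms",
         call. = FALSE)
  }
  structure(prof, class = "subject_profile")
}

STIM_KINDS <- c("nontarget", "target", "distractor")

kind_to_code <- function(kind, config) {
  codes <- c(nontarget = config$nontarget_code,
             target = config$target_code,
             distractor = config$distractor_code)
  unname(codes[kind])
}

#' Generate a stimulus sequence
#'
#' Draws `n_events` i.i.d. stimulus kinds with the configured probabilities,
#' spaced exactly `stim_interval` apart starting one interval into the
#' recording.
#'
#' @param config A [sim_config()].
#' @param n_events Number of stimulus events (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `onset_sample` (0-based sample index),
#'   `kind` (target/nontarget/distractor) and `code` (marker string).
#' @export
generate_stimulus_sequence <- function(config, n_events, seed) {
  stopifnot(inherits(config, "sim_config"))
  n_events <- check_count(n_events, "n_events")
  kinds <- with_seed(seed, sample(STIM_KINDS, n_events, replace = TRUE,
                                  prob = c(config$p_nontarget, config$p_target,
                                           config$p_distractor)))
  spacing <- round(config$stim_interval * config$sampling_rate)
  onsets <- spacing + (seq_len(n_events) - 1L) * spacing
  data.frame(onset_sample = as.integer(onsets), kind = kinds,
             code = kind_to_code(kinds, config), stringsAsFactors = FALSE)
}

# spectral scaling for 1/f shaping at smooth FFT length m
pink_scale_vector <- function(m, exponent) {
  k <- 0:(m - 1)
  f <- pmin(k, m - k)        # symmetric frequency index
  s <- c(0, 1 / f[-1]^(exponent / 2))   # DC removed -> zero-mean output
  s
}

# one channel of unit-variance 1/f noise via spectral shaping; the FFT runs
# at the next 2-3-5-smooth length and the result is truncated to n
pink_channel <- function(n, exponent, scale = NULL) {
  if (n < 4) return(stats::rnorm(n))
  m <- stats::nextn(n, c(2, 3, 5))
  if (is.null(scale)) scale <- pink_scale_vector(m, exponent)
  w <- stats::rnorm(m)
  x <- stats::fft(w)
  y <- Re(stats::fft(x * scale, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate background EEG activity
#'
#' Zero-mean stochastic signal per channel combining 1/f noise, an
#' alpha-band sinusoid with random per-channel phase, and white noise,
#' with component amplitudes taken from the config's [noise_model()].
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed.
#' @return Numeric matrix, channels x samples, in uV.
#' @export
generate_background <- function(config, n_samples, seed) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- check_count(n_samples, "n_samples")
  nm <- config$noise_model
  nc <- config$n_channels
  fs <- config$sampling_rate
  scale <- if (nm$pink_sd > 0 && n_samples >= 4) {
    pink_scale_vector(stats::nextn(n_samples, c(2, 3, 5)), nm$pink_exponent)
  } else NULL
  with_seed(seed, {
    # fill samples x channels (contiguous column writes), transpose once
    sig <- matrix(0, n_samples, nc)
    t_sec <- (seq_len(n_samples) - 1) / fs
    for (ch in seq_len(nc)) {
      v <- numeric(n_samples)
      if (nm$pink_sd > 0) {
        v <- v + nm$pink_sd * pink_channel(n_samples, nm$pink_exponent, scale)
      }
      if (nm$alpha_amplitude > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        v <- v + nm$alpha_amplitude * sin(2 * pi * nm$alpha_freq * t_sec + phase)
      }
      if (nm$white_sd > 0) {
        v <- v + stats::rnorm(n_samples, sd = nm$white_sd)
      }
      sig[, ch] <- v
    }
    t(sig)
  })
}

# Gaussian response kernel over the post-stimulus span; peak exactly at the
# sample grid point nearest `latency` when latency is an integer ms at 1 kHz.
response_kernel <- function(amplitude, latency_ms, width_ms, span_ms, fs) {
  n <- round(span_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  amplitude * exp(-((t_ms - latency_ms)^2) / (2 * width_ms^2))
}

#' Stimulus-evoked additive response waveform
#'
#' Target stimuli evoke a smooth unimodal (Gaussian) positivity at the
#' profile's latency (optionally jittered), scaled per channel by the
#' topography; non-targets evoke nothing; distractors evoke a P3a only if
#' the profile defines one.
#'
#' @param profile A [subject_profile()].
#' @param kind One of "target", "nontarget", "distractor".
#' @param config A [sim_config()].
#' @param seed Integer seed for the latency jitter draw; `NULL` disables
#'   jitter (the mean latency is used).
#' @return Matrix channels x span-samples (uV) to be added at stimulus onset.
#' @export
generate_event_response <- function(profile, kind, config, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "sim_config"))
  kind <- match.arg(kind, STIM_KINDS)
  fs <- config$sampling_rate
  span <- profile$response_span_ms
  n <- round(span * fs / 1000)
  zero <- matrix(0, config$n_channels, n)
  if (kind == "nontarget") return(zero)
  if (kind == "distractor") {
    dr <- profile$distractor_response
    if (is.null(dr)) return(zero)
    k <- response_kernel(dr$amplitude, dr$latency, dr$width, span, fs)
    return(outer(as.numeric(dr$topography), k))
  }
  lat <- profile$p300_latency
  if (!is.null(seed) && profile$latency_jitter_sd > 0) {
    lat <- lat + with_seed(seed, stats::rnorm(1, 0, profile$latency_jitter_sd))
  }
  k <- response_kernel(profile$p300_amplitude, lat, profile$p300_width, span, fs)
  outer(as.numeric(profile$topography), k)
}

# draw stimulus kinds one phase at a time until the target quota is met;
# chunked sampling keeps this vectorized yet deterministic under the seed
draw_phase_kinds <- function(config, quota) {
  kinds <- character(0)
  n_targets <- 0L
  repeat {
    chunk <- sample(STIM_KINDS, 4L * quota + 16L, replace = TRUE,
                    prob = c(config$p_nontarget, config$p_target,
                             config$p_distractor))
    kinds <- c(kinds, chunk)
    hits <- which(kinds == "target")
    if (length(hits) >= quota) {
      return(kinds[seq_len(hits[quota])])   # phase ends on its last target
    }
  }
}

#' Simulate one complete oddball session
#'
#' Generates the per-phase stimulus stream (each phase runs until its target
#' quota is reached), the background activity, and superposes the
#' target-locked (and optional distractor-locked) responses. Phases are
#' concatenated into one continuous recording; phase boundaries are recorded
#' as metadata.
#'
#' @param config A [sim_config()].
#' @param profile A [subject_profile()].
#' @param seed Integer seed; sub-streams for the stimulus sequence,
#'   background, and latency jitter are derived from it, so a session with
#'   amplitude zero shares its background and marker track sample-for-sample
#'   with the same-seed session at any amplitude.
#' @return An `erp_recording` (see [extract_epochs()] for the epoching side).
#' @export
simulate_session <- function(config, profile, seed) {
  stopifnot(inherits(config, "sim_config"), inherits(profile, "subject_profile"))
  if (config$n_channels != profile$n_channels) {
    stop("config and profile disagree on n_channels", call. = FALSE)
  }
  fs <- config$sampling_rate
  spacing <- round(config$stim_interval * fs)

  kinds <- character(0)
  phase_last_event <- integer(0)
  for (p in seq_len(config$n_phases)) {
    ph <- with_seed(derive_seed(seed, 100 + p),
                    draw_phase_kinds(config, config$targets_per_phase))
    kinds <- c(kinds, ph)
    phase_last_event <- c(phase_last_event, length(kinds))
  }
  n_events <- length(kinds)
  onsets <- spacing + (seq_len(n_events) - 1L) * spacing
  span_samples <- round(profile$response_span_ms * fs / 1000)
  n_samples <- onsets[n_events] + span_samples + round(0.5 * fs)

  signal <- generate_background(config, n_samples, derive_seed(seed, 2))

  jitters <- if (profile$latency_jitter_sd > 0) {
    with_seed(derive_seed(seed, 3),
              stats::rnorm(n_events, 0, profile$latency_jitter_sd))
  } else {
    rep(0, n_events)
  }

  # responses are accumulated sparsely and added in one subset assignment;
  # event windows never overlap (span <= stimulus spacing)
  top <- as.numeric(profile$topography)
  active <- which((kinds == "target" & profile$p300_amplitude > 0) |
                  (kinds == "distractor" & !is.null(profile$distractor_response)))
  if (length(active)) {
    resp_cols <- integer(length(active) * span_samples)
    resp_vals <- matrix(0, config$n_channels, length(active) * span_samples)
    at <- 0L
    for (i in active) {
      block <- if (kinds[i] == "target") {
        outer(top, response_kernel(profile$p300_amplitude,
                                   profile$p300_latency + jitters[i],
                                   profile$p300_width, profile$response_span_ms, fs))
      } else {
        dr <- profile$distractor_response
        outer(as.numeric(dr$topography),
              response_kernel(dr$amplitude, dr$latency, dr$width,
                              profile$response_span_ms, fs))
      }
      resp_cols[at + seq_len(span_samples)] <- (onsets[i] + 1L):(onsets[i] + span_samples)
      resp_vals[, at + seq_len(span_samples)] <- block
      at <- at + span_samples
    }
    signal[, resp_cols] <- signal[, resp_cols] + resp_vals
  }

  markers <- data.frame(onset_sample = as.integer(onsets),
                        code = kind_to_code(kinds, config),
                        stringsAsFactors = FALSE)
  new_recording(signal = signal, sampling_rate = fs,
                channel_labels = channel_labels_1020(config$n_channels),
                markers = markers,
                metadata = list(subject_id = profile$subject_id,
                                seed = as.integer(seed),
                                phase_last_event = phase_last_event,
                                kinds = kinds))
}

#' Simulate a cohort of independent sessions
#'
#' One session per profile; per-subject seeds are derived deterministically
#' from the master seed, so the i-th subject's recording depends only on the
#' master seed, the config and their profile.
#'
#' @param config A [sim_config()] shared by the cohort.
#' @param profiles Non-empty list of [subject_profile()] objects.
#' @param seed Master integer seed.
#' @return List of `erp_recording` objects, one per profile.
#' @export
simulate_cohort <- function(config, profiles, seed) {
  if (length(profiles) < 1L) {
    stop("`profiles` must contain at least one subject profile", call. = FALSE)
  }
  lapply(seq_along(profiles), function(i) {
    simulate_session(config, profiles[[i]], derive_seed(seed, 1000 + i))
  })
}

#' Subject seed used by [simulate_cohort()] for cohort position `i`
#' @param seed Master seed.
#' @param i Cohort position (1-based).
#' @return Integer seed.
#' @export
cohort_subject_seed <- function(seed, i) derive_seed(seed, 1000 + i)
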