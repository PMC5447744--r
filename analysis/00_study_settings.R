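# Shared settings for the numbered analysis scripts: the simulated study
# cohort (4 training + 11 testing subjects at the oddball protocol), the
# feature and classifier parameters, and the output locations.
#
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_extract_features.R
#   Rscript analysis/03_train_classifiers.R
#   Rscript analysis/04_evaluate.R

library(p300sae)

MASTER_SEED <- 20170530L
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
MODEL_DIR <- file.path(RESULTS_DIR, "models")

# Recording/protocol settings at the study defaults: 19 channels, 1 kHz,
# 1 Hz stimulation at 83/13.5/3.5% probabilities, 3 phases x 30 targets.
# The background model mixes 1/f, alpha and white components at amplitudes
# that leave a realistic single-trial signal-to-noise ratio.
STUDY_SIM <- sim_config()

# 15 subjects with conventional P300 variability: peak amplitudes 2-10 uV,
# latencies 350-450 ms, 30 ms trial-to-trial jitter. The first four form the
# training pool, the remaining eleven are held-out test subjects.
STUDY_PROFILES <- make_cohort_profiles(15, seed = MASTER_SEED)
TRAIN_IDX <- 1:4
TEST_IDX <- 5:15

STUDY_CONFIG <- study_config(
  sim = STUDY_SIM,
  profiles_train = STUDY_PROFILES[TRAIN_IDX],
  profiles_test = STUDY_PROFILES[TEST_IDX],
  seed = MASTER_SEED
)

feature_pipeline <- function(epochs, fp = STUDY_CONFIG$feature_params) {
  normalize_rows(windowed_means(baseline_correct(epochs, fp$baseline_ms),
                                fp$start_ms, fp$end_ms, fp$width_ms))
}

ensure_dirs <- function() {
  for (d in c(RESULTS_DIR, DATA_DIR, MODEL_DIR)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
}
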