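#' Configuration for synthetic cohort generation
#'
#' @param contrast Lesion-absorption class mapping passed to
#'   [sample_phantom()] ("gap" or "overlap").
#' @param n_repeats Repeated lesion measurements per case.
#' @param probe_jitter_sd,amp_noise_sd,phase_noise_sd_deg Acquisition
#'   noise model (see [simulate_measurements()]).
#' @param geometry Probe geometry.
#' @param wavelengths Acquisition wavelengths, nm.
#' @param scattering_model Forward composition ("rytov" or "born"), see
#'   [simulate_measurements()].
#' @param hist_real_range,hist_imag_range Histogram axis ranges.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(contrast = "gap", n_repeats = 3,
                          probe_jitter_sd = 0.25, amp_noise_sd = 0.01,
                          phase_noise_sd_deg = 0.5,
                          geometry = default_probe_geometry(),
                          wavelengths = default_wavelengths(),
                          scattering_model = "rytov",
                          hist_real_range = c(-1, 1),
                          hist_imag_range = c(-1, 1)) {
  structure(list(contrast = contrast, n_repeats = n_repeats,
                 probe_jitter_sd = probe_jitter_sd,
                 amp_noise_sd = amp_noise_sd,
                 phase_noise_sd_deg = phase_noise_sd_deg,
                 geometry = geometry, wavelengths = wavelengths,
                 scattering_model = scattering_model,
                 hist_real_range = hist_real_range,
                 hist_imag_range = hist_imag_range),
            class = "cohort_config")
}

#' Generate a labelled synthetic patient cohort
#'
#' Per case: sample a class-conditional phantom, simulate frequency-
#' domain measurements with probe jitter and noise, compute the
#' perturbation and its 32 x 32 histogram, and fix the seed of the
#' surrogate ultrasound image (images themselves are rendered on demand
#' by [case_us_image()] to keep cohorts light). Reconstruction is
#' deferred: in the two-stage workflow only suspicious cases are ever
#' reconstructed.
#'
#' @param n_benign,n_malignant Class counts.
#' @param seed Master seed; the cohort is a pure function of it.
#' @param config A [cohort_config()].
#' @param us_images Whether cases carry an ultrasound surrogate
#'   (DOT-only pretraining cohorts do not).
#' @return List of `synthetic_case` objects.
#' @export
build_cohort <- function(n_benign, n_malignant, seed = 1,
                         config = cohort_config(), us_images = TRUE) {
  stopifnot(n_benign >= 1, n_malignant >= 1)
  set.seed(seed)
  n <- n_benign + n_malignant
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  case_seeds <- sample.int(2^31 - 10, n)
  lapply(seq_len(n), function(i) {
    ph <- sample_phantom(labels[i], seed = case_seeds[i],
                         contrast = config$contrast,
                         n_wavelengths = length(config$wavelengths))
    ms <- simulate_measurements(ph, config$geometry, config$wavelengths,
                                n_repeats = config$n_repeats,
                                probe_jitter_sd = config$probe_jitter_sd,
                                amp_noise_sd = config$amp_noise_sd,
                                phase_noise_sd_deg = config$phase_noise_sd_deg,
                                scattering_model = config$scattering_model,
                                seed = case_seeds[i] + 1L)
    hist <- build_histogram(compute_perturbation(ms),
                            real_range = config$hist_real_range,
                            imag_range = config$hist_imag_range)
    structure(list(case_id = sprintf("case_%04d", i), label = labels[i],
                   phantom = ph, measurements = ms, histogram = hist,
                   us_seed = if (us_images) case_seeds[i] + 2L else NULL,
                   thb = NULL),
              class = "synthetic_case")
  })
}

#' Render the surrogate ultrasound image of a case
#'
#' Deterministic given the case (the image seed is fixed at cohort
#' generation).
#'
#' @param case A `synthetic_case` built with `us_images = TRUE`.
#' @param pixel_pitch Pixel size, mm.
#' @return A `us_image`.
#' @export
case_us_image <- function(case, pixel_pitch = 0.1) {
  if (is.null(case$us_seed)) stop("case has no ultrasound surrogate")
  generate_us_image(case$label, case$phantom$lesion_radius,
                    case$phantom$lesion_center[3], pixel_pitch,
                    seed = case$us_seed)
}

#' Case labels / ids of a cohort
#' @param cohort A list of `synthetic_case` objects.
#' @return Character vector.
#' @export
cohort_labels <- function(cohort)
  vapply(cohort, `[[`, character(1), "label")

#' @rdname cohort_labels
#' @export
cohort_ids <- function(cohort)
  vapply(cohort, `[[`, character(1), "case_id")

#' Balanced bootstrap train/test splits
#'
#' Each run independently samples, without replacement within the run,
#' a balanced training set (`n_train` per class) and a disjoint balanced
#' testing set (`n_test` per class).
#'
#' @param cohort A cohort list or a character/factor label vector (named
#'   by case id, or ids default to the index).
#' @param n_runs Number of bootstrap runs.
#' @param seed Master seed.
#' @param n_train,n_test Per-class sizes of the training / testing sets.
#' @return List of splits: `run_index`, `train_ids`, `test_ids`.
#' @export
make_bootstrap_splits <- function(cohort, n_runs = 50, seed = 1,
                                  n_train = 60, n_test = 25) {
  if (is.list(cohort)) {
    labels <- cohort_labels(cohort)
    ids <- cohort_ids(cohort)
  } else {
    labels <- as.character(cohort)
    ids <- names(cohort)
    if (is.null(ids)) ids <- as.character(seq_along(labels))
  }
  ben <- ids[labels == "benign"]; mal <- ids[labels == "malignant"]
  need <- n_train + n_test
  if (length(ben) < need || length(mal) < need)
    stop(sprintf("need at least %d cases per class", need))
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    b <- sample(ben, need); m <- sample(mal, need)
    list(run_index = r - 1L,
         train_ids = c(b[seq_len(n_train)], m[seq_len(n_train)]),
         test_ids = c(b[n_train + seq_len(n_test)],
                      m[n_train + seq_len(n_test)]))
  })
}
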