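#' Simulation parameters for the paired wearable/Holter cohort generator
#'
#' Defines the generative model used to exercise the whole pipeline without
#' patient data: a two-state (AF/sinus) semi-Markov rhythm process built from
#' an inhomogeneous Poisson stream of episode onsets with circadian rate
#' modulation, a three-component lognormal episode-duration mixture spanning
#' the <6 min / 6 min-1 h / >=1 h strata, state-dependent pulse rates, and a
#' device channel that masks epochs as motion artifact and perturbs the
#' per-epoch AF probability.
#'
#' @param n_subjects number of subjects (>= 2; weight derivation needs
#'   between-subject variance).
#' @param days_per_subject monitoring days per subject (default 1, the
#'   24-hour Holter window).
#' @param base_onset_rate cohort-median AF episode onset rate, episodes/hour.
#' @param onset_rate_sdlog sdlog of the lognormal subject-level frailty
#'   multiplying `base_onset_rate`; creates the wide between-subject burden
#'   dispersion (many near-zero, some near-persistent) seen in paroxysmal AF
#'   cohorts. Set 0 for a homogeneous cohort.
#' @param circadian_amplitude relative amplitude in `[0, 1)` of the cosine
#'   modulation of the onset rate.
#' @param circadian_phase_hr clock hour of peak onset rate (default 3, i.e.
#'   nocturnal onset dominance, which yields the negative day/night contrast
#'   typical of paroxysmal AF).
#' @param duration_weights mixture weights of the three lognormal duration
#'   components (must sum to 1).
#' @param duration_meanlog,duration_sdlog log-scale parameters of the three
#'   components (minutes), targeting short (<6 min), sustained (6 min-1 h)
#'   and prolonged (>=1 h) episodes.
#' @param sinus_hr_mean,sinus_hr_sd pulse rate (bpm) during sinus rhythm.
#' @param af_hr_mean,af_hr_sd pulse rate (bpm) during AF (tachycardic shift).
#' @param tachy_floor_bpm the tachycardia threshold used downstream; kept in
#'   the parameter set for documentation, the generator itself does not clip
#'   rates at it.
#' @param artifact_rate_day,artifact_rate_night probability that an epoch of
#'   the index device is masked `INVALID` in the day / night clock window.
#'   Defaults (0.10 / 0.02) encode daytime-dominant residual motion masking
#'   after upstream signal-quality optimization.
#' @param ref_artifact_rate artifact probability of the reference device
#'   (Holter leads detach rarely; classifier noise is zero on the reference).
#' @param af_prob_clean,sinus_prob_clean the index classifier's noiseless
#'   operating probabilities for AF and sinus epochs (defaults 0.85 / 0.15):
#'   a realistic per-epoch detector emits graded confidence, not hard 0/1,
#'   and this margin is what classifier noise perturbs.
#' @param classifier_noise_sd sd of additive Gaussian noise on the index
#'   device's per-epoch AF probability (clamped to `[0, 1]`).
#' @param classifier_flip_prob probability of hard label/probability
#'   inversion, the worst-case noise mode (default 0; used by stress tests).
#' @param event_alpha,event_beta intercept and slope of the logistic link
#'   from true normalized burden to the probability of an AF-related clinical
#'   event.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_subjects = 110L,
                       days_per_subject = 1L,
                       base_onset_rate = 0.08,
                       onset_rate_sdlog = 1.5,
                       circadian_amplitude = 0.5,
                       circadian_phase_hr = 3,
                       duration_weights = c(0.35, 0.40, 0.25),
                       duration_meanlog = log(c(2, 20, 180)),
                       duration_sdlog = c(0.5, 0.6, 0.7),
                       sinus_hr_mean = 75, sinus_hr_sd = 10,
                       af_hr_mean = 105, af_hr_sd = 22,
                       tachy_floor_bpm = 120,
                       artifact_rate_day = 0.10,
                       artifact_rate_night = 0.02,
                       ref_artifact_rate = 0.01,
                       af_prob_clean = 0.85,
                       sinus_prob_clean = 0.15,
                       classifier_noise_sd = 0.15,
                       classifier_flip_prob = 0,
                       event_alpha = -2, event_beta = 4) {
  p <- as.list(environment())
  stopifnot(p$n_subjects >= 1, p$days_per_subject >= 1,
            p$base_onset_rate >= 0,
            p$circadian_amplitude >= 0, p$circadian_amplitude < 1,
            p$circadian_phase_hr >= 0, p$circadian_phase_hr < 24,
            length(p$duration_weights) == 3L,
            abs(sum(p$duration_weights) - 1) < 1e-9,
            all(p$duration_weights >= 0),
            p$artifact_rate_day >= 0, p$artifact_rate_day <= 1,
            p$artifact_rate_night >= 0, p$artifact_rate_night <= 1,
            p$ref_artifact_rate >= 0, p$ref_artifact_rate <= 1,
            p$af_prob_clean >= 0, p$af_prob_clean <= 1,
            p$sinus_prob_clean >= 0, p$sinus_prob_clean <= 1,
            p$classifier_noise_sd >= 0,
            p$classifier_flip_prob >= 0, p$classifier_flip_prob <= 1)
  # guard against a process that would saturate the stream with AF
  mean_dur <- sum(p$duration_weights *
                    exp(p$duration_meanlog + p$duration_sdlog^2 / 2))
  expected_burden <- p$base_onset_rate * mean_dur / 60
  if (expected_burden >= 1) {
    stop("expected AF burden >= 1; reduce base_onset_rate or episode durations",
         call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

# one RNG substream per (seed, subject, purpose); keeps every draw reproducible
# and independent of evaluation order while staying inside 32-bit integers
subject_seed <- function(seed, subject_index, offset = 0L) {
  (as.integer(seed) %% 100000L) * 20011L + subject_index * 17L + offset
}

#' Simulate one subject's noiseless rhythm stream
#'
#' Episode onsets follow an inhomogeneous Poisson process with rate
#' `lambda(t) = rate * (1 + A * cos(2*pi*(t - phase)/24h))`, thinned per
#' minute; durations are drawn from the lognormal mixture and overlapping
#' episodes merge. Pulse rate is drawn per epoch from the sinus or AF
#' distribution according to the rhythm state. The returned stream is the
#' noiseless truth: every epoch is valid, `prob_af` is 0/1, quality is 1.
#'
#' @param params a [sim_params()] object.
#' @param subject_index positive integer; together with `seed` it fully
#'   determines the stream (bit-identical on replay).
#' @param seed integer master seed.
#' @return A list with elements `stream` (the truth [epoch_stream()]) and
#'   `onset_rate` (the subject's realized episodes/hour rate).
#' @export
simulate_subject <- function(params, subject_index, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  n_min <- params$days_per_subject * 1440L
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  times <- t0 + 60 * (seq_len(n_min) - 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  set.seed(subject_seed(seed, subject_index, 0L))
  frailty <- if (params$onset_rate_sdlog > 0) {
    stats::rlnorm(1, meanlog = -params$onset_rate_sdlog^2 / 2,
                  sdlog = params$onset_rate_sdlog)
  } else 1
  rate <- params$base_onset_rate * frailty

  hr_of_min <- ((seq_len(n_min) - 1) %/% 60) %% 24 + 0.5 # mid-hour clock time
  lambda_min <- rate / 60 *
    (1 + params$circadian_amplitude *
       cos(2 * pi * (hr_of_min - params$circadian_phase_hr) / 24))
  lambda_min <- pmin(lambda_min, 1) # Bernoulli thinning cap
  onsets <- which(stats::runif(n_min) < lambda_min)

  af <- logical(n_min)
  if (length(onsets) > 0) {
    comp <- sample.int(3L, length(onsets), replace = TRUE,
                       prob = params$duration_weights)
    dur <- pmax(1L, round(stats::rlnorm(length(onsets),
                                        params$duration_meanlog[comp],
                                        params$duration_sdlog[comp])))
    for (j in seq_along(onsets)) {
      af[onsets[j]:min(n_min, onsets[j] + dur[j] - 1L)] <- TRUE
    }
  }

  pulse <- ifelse(af,
                  stats::rnorm(n_min, params$af_hr_mean, params$af_hr_sd),
                  stats::rnorm(n_min, params$sinus_hr_mean, params$sinus_hr_sd))
  pulse <- pmax(pulse, 30)

  stream <- epoch_stream(times,
                         label = ifelse(af, "AF", "SINUS"),
                         prob_af = as.numeric(af),
                         pulse_bpm = pulse,
                         quality = 1,
                         subject_id = sprintf("S%04d", subject_index),
                         device = "INDEX")
  list(stream = stream, onset_rate = rate)
}

#' Pass a truth stream through a device's observation channel
#'
#' Epochs are independently masked `INVALID` with the day/night artifact
#' rates; surviving epochs get the classifier's clean operating probability
#' for their true rhythm (`af_prob_clean` / `sinus_prob_clean`) perturbed by
#' additive Gaussian classifier noise (clamped to `[0, 1]`), or inverted with
#' `classifier_flip_prob` in the hard-flip stress mode. The provisional label
#' thresholds the noisy probability at 0.5 (contextual fusion re-decides
#' downstream). The reference device uses `ref_artifact_rate` in both windows
#' and zero classifier noise.
#'
#' @param truth a noiseless truth [epoch_stream()] from [simulate_subject()].
#' @param params a [sim_params()] object.
#' @param device `"INDEX"` or `"REFERENCE"`.
#' @param seed,subject_index determine the channel randomness.
#' @return An observed [epoch_stream()].
#' @export
degrade_to_device <- function(truth, params, device = c("INDEX", "REFERENCE"),
                              seed = 1L, subject_index = 1L) {
  device <- match.arg(device)
  n <- nrow(truth)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(seed, subject_index,
                        if (device == "INDEX") 1L else 2L))

  day <- is_daytime(truth)
  art_rate <- if (device == "INDEX") {
    ifelse(day, params$artifact_rate_day, params$artifact_rate_night)
  } else rep(params$ref_artifact_rate, n)
  invalid <- stats::runif(n) < art_rate

  prob <- truth$prob_af
  if (device == "INDEX") {
    # noiseless classifier operating margin, then additive noise
    prob <- ifelse(truth$label == "AF",
                   params$af_prob_clean, params$sinus_prob_clean)
    if (params$classifier_flip_prob > 0) {
      flip <- stats::runif(n) < params$classifier_flip_prob
      prob[flip] <- 1 - prob[flip]
    }
    if (params$classifier_noise_sd > 0) {
      prob <- prob + stats::rnorm(n, 0, params$classifier_noise_sd)
    }
    prob <- pmin(1, pmax(0, prob))
  }

  quality <- ifelse(invalid, stats::runif(n, 0, 0.4), stats::runif(n, 0.6, 1))
  label <- ifelse(invalid, "INVALID", ifelse(prob >= 0.5, "AF", "SINUS"))
  prob[invalid] <- NA_real_
  pulse <- truth$pulse_bpm
  pulse[invalid] <- NA_real_

  epoch_stream(truth$start_time, label, prob, pulse, quality,
               subject_id = attr(truth, "subject_id"), device = device)
}

#' Simulate a paired wearable/Holter cohort with clinical labels
#'
#' Runs [simulate_subject()] and [degrade_to_device()] per subject and
#' attaches clinical labels: `event_flag ~ Bernoulli(plogis(alpha + beta *
#' burden))` on the true normalized burden, EHRA symptom class from monotone
#' quartile binning of true burden with 10% ordinal jitter (class "0" for
#' zero-burden subjects), plus a risk-profile and treatment draw.
#'
#' @param params a [sim_params()] object (`n_subjects >= 2`).
#' @param seed integer master seed; all randomness flows from it.
#' @return A list of class `"af_cohort"`: `truth`, `index`, `reference`
#'   (lists of epoch streams, one per subject), `clinical` (one row per
#'   subject: `subject_id`, `true_burden`, `ehra_class`, `event_flag`,
#'   `risk_profile`, `treatment`), and `params`.
#' @export
simulate_cohort <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_subjects < 2L) {
    stop("cohort simulation needs n_subjects >= 2", call. = FALSE)
  }
  n <- params$n_subjects
  truth <- index <- reference <- vector("list", n)
  burden <- numeric(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    sim <- simulate_subject(params, i, seed)
    truth[[i]] <- sim$stream
    index[[i]] <- degrade_to_device(sim$stream, params, "INDEX", seed, i)
    reference[[i]] <- degrade_to_device(sim$stream, params, "REFERENCE", seed, i)
    burden[i] <- mean(sim$stream$label == "AF")
    ids[i] <- attr(sim$stream, "subject_id")
  }
  names(truth) <- names(index) <- names(reference) <- ids

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(seed, 0L, 3L))

  event <- stats::runif(n) < stats::plogis(params$event_alpha +
                                             params$event_beta * burden)
  ehra <- ehra_from_burden(burden, jitter_prob = 0.1)
  risk <- sample(c("rhythm_rate", "thromboembolism", "other"), n,
                 replace = TRUE, prob = c(0.6, 0.1, 0.3))
  treatment <- sample(c("none", "drug", "ablation"), n,
                      replace = TRUE, prob = c(0.5, 0.3, 0.2))
  clinical <- data.frame(subject_id = ids, true_burden = burden,
                         ehra_class = ehra, event_flag = event,
                         risk_profile = risk, treatment = treatment,
                         stringsAsFactors = FALSE)
  structure(list(truth = truth, index = index, reference = reference,
                 clinical = clinical, params = params, seed = seed),
            class = "af_cohort")
}

# monotone quartile binning of positive burden into EHRA I-IV with ordinal
# jitter; zero-burden subjects are class 0
ehra_from_burden <- function(burden, jitter_prob = 0.1) {
  cls <- integer(length(burden))
  pos <- burden > 0
  if (any(pos)) {
    q <- stats::quantile(burden[pos], c(0.25, 0.5, 0.75), names = FALSE)
    cls[pos] <- 1L + findInterval(burden[pos], q)
    jit <- pos & stats::runif(length(burden)) < jitter_prob
    cls[jit] <- pmin(4L, pmax(1L, cls[jit] +
                                sample(c(-1L, 1L), sum(jit), replace = TRUE)))
  }
  ordered(c("0", "I", "II", "III", "IV")[cls + 1L],
          levels = c("0", "I", "II", "III", "IV"))
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
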