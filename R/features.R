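#' Episode-frequency features
#'
#' The three frequency ("number") metrics of the 5D progression model, all on
#' a per-valid-epoch denominator: the instantaneous AF burden ratio (AF
#' epochs / valid epochs), the sustained-episode ratio (episodes >= 6 min /
#' valid epochs) and the prolonged-episode ratio (episodes >= 1 h / valid
#' epochs).
#'
#' @param episodes an episode list from [extract_episodes()].
#' @param acct a [time_accounting()] list.
#' @return Named list `af_epoch_ratio`, `episodes_ge6_ratio`,
#'   `episodes_ge1h_ratio`; all `NA` when `n_valid` is 0 (undefined, not 0).
#' @export
number_features <- function(episodes, acct) {
  if (acct$n_valid == 0L) {
    return(list(af_epoch_ratio = NA_real_, episodes_ge6_ratio = NA_real_,
                episodes_ge1h_ratio = NA_real_))
  }
  list(af_epoch_ratio = sum(episodes$n_af_epochs) / acct$n_valid,
       episodes_ge6_ratio = sum(episodes$duration_min >= 6) / acct$n_valid,
       episodes_ge1h_ratio = sum(episodes$duration_min >= 60) / acct$n_valid)
}

#' Episode-duration (burden) features
#'
#' Overall AF burden (total AF time / valid time) and its restrictions to
#' sustained (episodes >= 6 min) and prolonged (>= 1 h) episodes. AF time is
#' counted in AF-labeled epochs only, so bridged invalid minutes never
#' inflate burden.
#'
#' @inheritParams number_features
#' @return Named list `burden_all`, `burden_ge6`, `burden_ge1h` with
#'   `burden_all >= burden_ge6 >= burden_ge1h`; all `NA` when `n_valid` is 0.
#' @export
duration_features <- function(episodes, acct) {
  if (acct$n_valid == 0L) {
    return(list(burden_all = NA_real_, burden_ge6 = NA_real_,
                burden_ge1h = NA_real_))
  }
  list(burden_all = sum(episodes$n_af_epochs) / acct$n_valid,
       burden_ge6 = sum(episodes$n_af_epochs[episodes$duration_min >= 6]) /
         acct$n_valid,
       burden_ge1h = sum(episodes$n_af_epochs[episodes$duration_min >= 60]) /
         acct$n_valid)
}

#' AF density: burst-like temporal clustering of AF time
#'
#' A Lorenz-type concentration index on `[0, 1]`. Let `u` index valid
#' monitoring time rescaled to the unit interval and `C(u)` the fraction of
#' total AF time accumulated by `u`. The index is
#' `integral |C(u) - u| du / ((1 - b) / 2)` with `b` the overall burden;
#' the normalizer is the integral attained when all AF time forms one block
#' at either end of monitoring, so the index is 0 for perfectly uniform AF
#' accumulation and 1 for maximal clustering. Defined 0 when `b` is 0 or 1.
#' Computed by trapezoid summation over the valid-epoch knots of the
#' piecewise-linear `C`.
#'
#' @param stream a labeled [epoch_stream()].
#' @return density in `[0, 1]`, `NA` if the stream has no valid epochs.
#' @export
af_density <- function(stream) {
  valid <- is_valid_epoch(stream)
  n <- sum(valid)
  if (n == 0L) return(NA_real_)
  af <- stream$label[valid] == "AF"
  n_af <- sum(af)
  b <- n_af / n
  if (n_af == 0L || n_af == n) return(0)
  u <- seq_len(n) / n
  d <- cumsum(af) / n_af - u        # signed deviation at the epoch knots
  d0 <- c(0, d[-n])
  # C - u is linear between knots, so each segment integrates exactly:
  # same-sign endpoints give the trapezoid, a sign crossing splits into two
  # triangles of area (d0^2 + d1^2) / (2 * (|d0| + |d1|))
  cross <- d0 * d < 0
  seg <- ifelse(cross,
                (d0^2 + d^2) / (2 * (abs(d0) + abs(d))),
                abs(d0 + d) / 2)
  integral <- sum(seg) / n
  integral / ((1 - b) / 2)
}

#' Circadian variability features
#'
#' Six clock-time metrics of AF temporal structure:
#' \describe{
#'   \item{cv_onset}{coefficient of variation (sample SD / mean) of episode
#'     onset clock times in minutes after midnight; needs >= 2 episodes.}
#'   \item{vom}{variation of the mean: the signed symmetric day/night
#'     contrast `(f_day - f_night) / (f_day + f_night)` of AF-epoch frequency
#'     per valid epoch, in `[-1, 1]` (0 when both windows are AF-free);
#'     negative values mean nocturnal AF dominance.}
#'   \item{af_variability}{day-to-day SD of per-day burden when at least two
#'     days carry >= 720 valid minutes each; otherwise the SD of the hourly
#'     burden series (the 24-hour Holter case).}
#'   \item{day_af_variability, night_af_variability}{SD of the hourly burden
#'     series restricted to the day / night window.}
#'   \item{arv}{average real variability: mean absolute difference of the
#'     hourly burden series over consecutive hours with valid data.}
#' }
#' The hourly burden series is AF minutes / valid minutes per clock hour,
#' over hours with at least one valid epoch.
#'
#' @param stream a labeled [epoch_stream()].
#' @param episodes its episode list.
#' @return Named list of the six metrics; fields that need more data than
#'   the stream provides are `NA`.
#' @export
circadian_features <- function(stream, episodes) {
  valid <- is_valid_epoch(stream)
  af <- stream$label == "AF"
  day <- is_daytime(stream)

  cv_onset <- NA_real_
  if (nrow(episodes) >= 2L) {
    onset_min <- as.numeric(format(episodes$onset, "%H")) * 60 +
      as.numeric(format(episodes$onset, "%M"))
    m <- mean(onset_min)
    if (m > 0) cv_onset <- stats::sd(onset_min) / m
  }

  f_day <- if (any(valid & day)) sum(af & valid & day) / sum(valid & day) else 0
  f_night <- if (any(valid & !day)) sum(af & valid & !day) / sum(valid & !day) else 0
  vom <- if (f_day + f_night == 0) 0 else (f_day - f_night) / (f_day + f_night)

  # hourly burden series over calendar hours with valid data
  hour_key <- format(stream$start_time, "%Y-%m-%d %H")
  hours <- unique(hour_key)
  v_per_h <- tapply(valid, hour_key, sum)[hours]
  af_per_h <- tapply(af & valid, hour_key, sum)[hours]
  has_data <- v_per_h > 0
  b_h <- ifelse(has_data, af_per_h / v_per_h, NA_real_)

  sd_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2L) stats::sd(x) else NA_real_
  }

  day_key <- format(stream$start_time, "%Y-%m-%d")
  v_per_d <- tapply(valid, day_key, sum)
  full_days <- names(v_per_d)[v_per_d >= 720]
  af_variability <- if (length(full_days) >= 2L) {
    af_per_d <- tapply(af & valid, day_key, sum)
    sd_or_na(as.numeric(af_per_d[full_days] / v_per_d[full_days]))
  } else {
    sd_or_na(b_h)
  }

  hour_clock <- as.integer(substr(hours, 12, 13))
  day_h <- hour_clock >= 6L & hour_clock < 22L

  arv <- NA_real_
  ok <- which(!is.na(b_h))
  if (length(ok) >= 2L) {
    # consecutive calendar hours only
    hr_abs <- as.numeric(as.POSIXct(paste0(hours, ":00:00"), tz = "UTC")) / 3600
    dif <- abs(diff(b_h[ok]))
    consec <- diff(hr_abs[ok]) == 1
    if (any(consec)) arv <- mean(dif[consec])
  }

  list(cv_onset = cv_onset, vom = vom, af_variability = af_variability,
       day_af_variability = sd_or_na(b_h[day_h]),
       night_af_variability = sd_or_na(b_h[!day_h]),
       arv = arv)
}

#' Tachycardia burden features
#'
#' Fraction of valid monitoring time (equivalently, of valid epochs, since
#' epochs are one minute) with pulse rate strictly above 120 bpm — the zone
#' associated with tachycardia-induced cardiomyopathy risk.
#'
#' @param stream an [epoch_stream()] with `pulse_bpm` on valid epochs.
#' @param threshold_bpm strict threshold (default 120).
#' @return Named list `tachy_duration_ratio`, `tachy_epoch_ratio` (identical
#'   under 1-minute epochs); `NA` when no valid epoch carries a pulse rate.
#' @export
tachycardia_features <- function(stream, threshold_bpm = 120) {
  valid <- is_valid_epoch(stream) & !is.na(stream$pulse_bpm)
  if (!any(valid)) {
    return(list(tachy_duration_ratio = NA_real_, tachy_epoch_ratio = NA_real_))
  }
  r <- sum(stream$pulse_bpm[valid] > threshold_bpm) / sum(valid)
  list(tachy_duration_ratio = r, tachy_epoch_ratio = r)
}

#' Names of the 15 spatiotemporal features, grouped by dimension
#' @return Named list of character vectors (`number`, `duration`,
#'   `aggregation`, `circadian`, `tachycardia`).
#' @export
feature_dimensions <- function() {
  list(number = c("af_epoch_ratio", "episodes_ge6_ratio", "episodes_ge1h_ratio"),
       duration = c("burden_all", "burden_ge6", "burden_ge1h"),
       aggregation = "af_density",
       circadian = c("cv_onset", "vom", "af_variability",
                     "day_af_variability", "night_af_variability", "arv"),
       tachycardia = c("tachy_duration_ratio", "tachy_epoch_ratio"))
}

#' Extract the full 5D feature vector from a labeled stream
#'
#' Runs episode extraction and all five feature groups; missing-field
#' semantics propagate (a feature that needs more data than the stream
#' provides is `NA`, never silently 0).
#'
#' @param stream a labeled [epoch_stream()] (typically the fused output).
#' @param bridging_gap_max passed to [extract_episodes()].
#' @return A one-row data.frame with the 15 feature columns plus
#'   `subject_id` and `device`.
#' @export
extract_features <- function(stream, bridging_gap_max = 3L) {
  acct <- time_accounting(stream)
  episodes <- extract_episodes(stream, bridging_gap_max)
  if (acct$n_valid == 0L) {
    f <- stats::setNames(as.list(rep(NA_real_, 15)),
                         unlist(feature_dimensions(), use.names = FALSE))
    return(cbind(data.frame(subject_id = attr(stream, "subject_id"),
                            device = attr(stream, "device"),
                            stringsAsFactors = FALSE),
                 as.data.frame(f)))
  }
  f <- c(number_features(episodes, acct),
         duration_features(episodes, acct),
         list(af_density = af_density(stream)),
         circadian_features(stream, episodes),
         tachycardia_features(stream))
  out <- as.data.frame(f)
  cbind(data.frame(subject_id = attr(stream, "subject_id"),
                   device = attr(stream, "device"),
                   stringsAsFactors = FALSE),
        out)
}

#' Feature table for a list of streams
#'
#' @param streams list of labeled [epoch_stream()] objects.
#' @param bridging_gap_max passed to [extract_episodes()].
#' @return data.frame, one row per stream.
#' @export
extract_feature_table <- function(streams, bridging_gap_max = 3L) {
  do.call(rbind, lapply(streams, extract_features,
                        bridging_gap_max = bridging_gap_max))
}
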