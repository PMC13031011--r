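#' Construct a per-minute epoch stream
#'
#' An epoch stream is the basic container of this package: one row per
#' 1-minute analysis window (left-closed, right-open) carrying a rhythm label,
#' an optional AF probability, an optional mean pulse rate and a signal
#' quality score. Timestamps are local clock time, because the circadian
#' features are clock-time constructs.
#'
#' @param start_time POSIXct vector, minute-aligned left edges of the windows.
#'   Must be strictly increasing with constant 1-minute spacing (use
#'   [read_epoch_csv()] to gap-fill raw exports).
#' @param label character vector, one of `"AF"`, `"SINUS"`, `"INVALID"`.
#' @param prob_af numeric in `[0, 1]` or `NA`, per-epoch AF probability.
#' @param pulse_bpm numeric `> 0` or `NA`, mean pulse rate of the epoch.
#' @param quality numeric in `[0, 1]`, signal quality score.
#' @param subject_id single string identifying the subject.
#' @param device `"INDEX"` (wearable) or `"REFERENCE"` (Holter).
#'
#' @return A data.frame of class `"epoch_stream"` with columns
#'   `start_time`, `label`, `prob_af`, `pulse_bpm`, `quality` and attributes
#'   `subject_id` and `device`.
#' @examples
#' t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
#' s <- epoch_stream(t0 + 60 * (0:3), c("AF", "AF", "SINUS", "AF"))
#' extract_episodes(s, bridging_gap_max = 0)
#' @export
epoch_stream <- function(start_time, label,
                         prob_af = NA_real_, pulse_bpm = NA_real_,
                         quality = 1,
                         subject_id = "S", device = "INDEX") {
  n <- length(start_time)
  if (!inherits(start_time, "POSIXct")) {
    stop("start_time must be POSIXct", call. = FALSE)
  }
  label <- as.character(label)
  stopifnot(length(label) == n)
  bad <- !label %in% c("AF", "SINUS", "INVALID")
  if (any(bad)) {
    stop("unknown rhythm label(s): ", paste(unique(label[bad]), collapse = ", "),
         call. = FALSE)
  }
  prob_af <- rep_len(as.numeric(prob_af), n)
  pulse_bpm <- rep_len(as.numeric(pulse_bpm), n)
  quality <- rep_len(as.numeric(quality), n)
  if (any(prob_af < 0 | prob_af > 1, na.rm = TRUE)) {
    stop("prob_af must lie in [0, 1]", call. = FALSE)
  }
  if (any(pulse_bpm <= 0, na.rm = TRUE)) {
    stop("pulse_bpm must be positive", call. = FALSE)
  }
  secs <- as.numeric(start_time)
  if (any(secs %% 60 != 0)) {
    stop("start_time must be aligned to whole minutes", call. = FALSE)
  }
  if (n > 1) {
    d <- diff(secs)
    if (any(d <= 0)) stop("start_time must be strictly increasing", call. = FALSE)
    if (any(d != 60)) {
      stop("epochs must be spaced exactly 1 minute apart; ",
           "gap-fill with INVALID epochs first (see read_epoch_csv)",
           call. = FALSE)
    }
  }
  device <- match.arg(device, c("INDEX", "REFERENCE"))
  out <- data.frame(start_time = start_time, label = label,
                    prob_af = prob_af, pulse_bpm = pulse_bpm,
                    quality = quality)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "device") <- device
  class(out) <- c("epoch_stream", "data.frame")
  out
}

#' @export
print.epoch_stream <- function(x, ...) {
  acct <- time_accounting(x)
  cat(sprintf("<epoch_stream> subject %s, device %s: %d epochs (%d valid), %d AF\n",
              attr(x, "subject_id"), attr(x, "device"),
              acct$n_total, acct$n_valid, sum(x$label == "AF")))
  NextMethod()
}

is_valid_epoch <- function(stream) stream$label != "INVALID"

#' Clock hour of each epoch
#' @noRd
epoch_hour <- function(stream) {
  as.integer(format(stream$start_time, "%H"))
}

#' Is each epoch in the daytime window?
#'
#' The day window is `[06:00, 22:00)` local clock time and the night window is
#' its complement `[22:00, 06:00)`; these windows drive the day/night split of
#' yield rates, circadian variability and the day/night burden contrast.
#'
#' @param stream an [epoch_stream()].
#' @return logical vector, `TRUE` for daytime epochs.
#' @export
is_daytime <- function(stream) {
  h <- epoch_hour(stream)
  h >= 6L & h < 22L
}

#' Valid-time accounting for an epoch stream
#'
#' Counts total and valid epochs and splits the valid count by the day
#' (`[06:00, 22:00)`) and night (`[22:00, 06:00)`) clock windows. Valid time is
#' the denominator of every burden ratio in the package: an `INVALID` epoch
#' contributes to total monitoring time but never to valid time.
#'
#' @param stream an [epoch_stream()].
#' @return A list with integer elements `n_total`, `n_valid`, `n_valid_day`,
#'   `n_valid_night` (the latter two partition `n_valid`).
#' @export
time_accounting <- function(stream) {
  valid <- is_valid_epoch(stream)
  day <- is_daytime(stream)
  list(n_total = nrow(stream),
       n_valid = sum(valid),
       n_valid_day = sum(valid & day),
       n_valid_night = sum(valid & !day))
}

#' Extract AF episodes from a labeled epoch stream
#'
#' An AF episode is a maximal run of `AF`-labeled epochs. Runs separated only
#' by short `INVALID` gaps (artifact dropouts) are merged into one episode: a
#' brief unreadable stretch should not fragment one physiological episode,
#' whereas a confirmed `SINUS` epoch always terminates the episode. The merged
#' episode's duration spans its first to its last AF epoch inclusive (bridged
#' invalid minutes inflate the duration but not the AF-epoch count).
#'
#' @param stream an [epoch_stream()].
#' @param bridging_gap_max maximum number of consecutive `INVALID` epochs that
#'   may be bridged inside one episode (default 3). `0` gives classical
#'   maximal-run extraction.
#' @return A data.frame of class `"episode_list"` with one row per episode:
#'   `onset` (POSIXct of the first AF epoch), `duration_min` (integer span,
#'   onset to last AF epoch inclusive) and `n_af_epochs` (AF epochs only).
#'   Ordered by onset, non-overlapping; attribute `bridging_gap_max`.
#' @examples
#' t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
#' s <- epoch_stream(t0 + 60 * (0:3), c("AF", "AF", "INVALID", "AF"))
#' extract_episodes(s, bridging_gap_max = 1) # one bridged 4-min episode
#' @export
extract_episodes <- function(stream, bridging_gap_max = 3L) {
  stopifnot(bridging_gap_max >= 0)
  lab <- stream$label
  af_idx <- which(lab == "AF")
  if (length(af_idx) == 0L) {
    return(empty_episode_list(bridging_gap_max))
  }
  # split AF epochs into episodes: break when the gap between consecutive AF
  # epochs exceeds the bridge, or when the gap contains any SINUS epoch
  breaks <- logical(length(af_idx))
  if (length(af_idx) > 1L) {
    for (j in 2:length(af_idx)) {
      gap <- af_idx[j] - af_idx[j - 1L] - 1L
      if (gap == 0L) next
      between <- lab[(af_idx[j - 1L] + 1L):(af_idx[j] - 1L)]
      breaks[j] <- gap > bridging_gap_max || any(between == "SINUS")
    }
  }
  grp <- cumsum(breaks)
  onset_i <- tapply(af_idx, grp, min)
  end_i <- tapply(af_idx, grp, max)
  n_af <- tapply(af_idx, grp, length)
  out <- data.frame(
    onset = stream$start_time[onset_i],
    duration_min = as.integer(end_i - onset_i + 1L),
    n_af_epochs = as.integer(n_af)
  )
  rownames(out) <- NULL
  attr(out, "bridging_gap_max") <- as.integer(bridging_gap_max)
  class(out) <- c("episode_list", "data.frame")
  out
}

empty_episode_list <- function(bridging_gap_max = 3L) {
  out <- data.frame(onset = as.POSIXct(character(), tz = "UTC"),
                    duration_min = integer(), n_af_epochs = integer())
  attr(out, "bridging_gap_max") <- as.integer(bridging_gap_max)
  class(out) <- c("episode_list", "data.frame")
  out
}
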