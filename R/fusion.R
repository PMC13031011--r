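#' Fusion configuration
#'
#' Parameters of the multiscale fusion stage: the quality gate, the symmetric
#' context window and its weights, and the decision threshold applied to the
#' fused AF probability.
#'
#' @param quality_min epochs with quality below this are relabeled `INVALID`
#'   before classification (default 0.5).
#' @param window_halfwidth half-width `W` of the context window in epochs
#'   (default 2, i.e. a 5-minute window; short enough that genuine <6-min
#'   episodes stay detectable).
#' @param neighbor_weights positive weights `w_0..w_W`, `w_0` for the epoch
#'   itself (default triangular `3, 2, 1`).
#' @param decision_threshold fused probability at or above which the epoch is
#'   labeled `AF` (default 0.5).
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(quality_min = 0.5, window_halfwidth = 2L,
                          neighbor_weights = NULL, decision_threshold = 0.5) {
  W <- as.integer(window_halfwidth)
  stopifnot(W >= 0L, quality_min >= 0, quality_min <= 1,
            decision_threshold > 0, decision_threshold < 1)
  if (is.null(neighbor_weights)) neighbor_weights <- seq(W + 1L, 1L)
  stopifnot(length(neighbor_weights) == W + 1L,
            all(is.finite(neighbor_weights)), all(neighbor_weights > 0))
  structure(list(quality_min = quality_min, window_halfwidth = W,
                 neighbor_weights = as.numeric(neighbor_weights),
                 decision_threshold = decision_threshold),
            class = "fusion_config")
}

#' Quality-gate an epoch stream
#'
#' Relabels epochs whose signal quality falls below `quality_min` as
#' `INVALID` (probability and pulse rate cleared); all other epochs pass
#' through unchanged. Idempotent.
#'
#' @param stream an [epoch_stream()].
#' @param quality_min threshold in `[0, 1]`.
#' @return The gated [epoch_stream()].
#' @export
gate_quality <- function(stream, quality_min = 0.5) {
  drop <- stream$quality < quality_min
  stream$label[drop] <- "INVALID"
  stream$prob_af[drop] <- NA_real_
  stream$pulse_bpm[drop] <- NA_real_
  stream
}

#' Reference per-epoch AF probability from interbeat intervals
#'
#' A deterministic, length-invariant irregularity score that satisfies the
#' per-epoch classifier contract (any epoch with >= 12 interbeat intervals
#' yields a probability in `[0, 1]`): it combines the dispersion of
#' normalized successive interbeat-interval differences with the Shannon
#' entropy of their histogram, mapped through a fixed logistic squashing.
#' Successive differences are taken circularly (wrapping last to first) so
#' the score depends only on the interval sequence's cyclic structure and is
#' exactly invariant under duplication of the sequence. This is an explicit
#' stand-in for a trained PPG classifier, not a clinical-grade detector.
#'
#' @param ibi_ms numeric vector of interbeat intervals in milliseconds, each
#'   in `[250, 2500]`; at least 12 intervals.
#' @return `prob_af` in `[0, 1]`, or `NA_real_` (insufficient data) when
#'   fewer than 12 intervals are supplied.
#' @examples
#' classify_epoch_reference(rep(800, 60))          # regular -> low
#' classify_epoch_reference(runif(60, 400, 1200))  # irregular -> high
#' @export
classify_epoch_reference <- function(ibi_ms) {
  ibi_ms <- as.numeric(ibi_ms)
  if (length(ibi_ms) < 12L) return(NA_real_)
  if (any(!is.finite(ibi_ms)) || any(ibi_ms < 250 | ibi_ms > 2500)) {
    stop("interbeat intervals must be finite and in [250, 2500] ms",
         call. = FALSE)
  }
  d <- abs(diff(c(ibi_ms, ibi_ms[1]))) / mean(ibi_ms) # circular differences
  rms <- sqrt(mean(d^2))
  breaks <- seq(0, 1, by = 0.125)
  p <- tabulate(findInterval(pmin(d, 1 - 1e-12), breaks,
                             rightmost.closed = TRUE), nbins = 8L)
  p <- p / sum(p)
  ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(8)
  stats::plogis(30 * rms + 2 * ent - 6)
}

#' Contextual fusion of per-epoch AF probabilities
#'
#' Calibrates each epoch's AF evidence by the temporal continuity of AF
#' episodes: the fused probability of a valid epoch is the weighted mean of
#' its own and its valid neighbors' probabilities within `+/- W` epochs
#' (invalid neighbors are excluded from numerator and denominator), and the
#' label is `AF` iff the fused probability reaches the decision threshold.
#' `INVALID` epochs are untouched. With `W = 0` fusion is the identity on
#' probabilities.
#'
#' @param stream an [epoch_stream()] with `prob_af` set on valid epochs.
#' @param cfg a [fusion_config()].
#' @return The fused [epoch_stream()]: `prob_af` replaced by the fused
#'   probabilities, labels re-decided.
#' @export
contextual_fuse <- function(stream, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"))
  n <- nrow(stream)
  valid <- is_valid_epoch(stream)
  prob <- stream$prob_af
  # fall back to the 0/1 label encoding where probabilities are absent
  miss <- valid & is.na(prob)
  prob[miss] <- as.numeric(stream$label[miss] == "AF")

  W <- cfg$window_halfwidth
  w <- cfg$neighbor_weights
  pv <- ifelse(valid, prob, 0)
  vv <- as.numeric(valid)
  num <- w[1] * pv
  den <- w[1] * vv
  if (W > 0) {
    for (k in seq_len(W)) {
      num <- num + w[k + 1] * (shift_fill0(pv, k) + shift_fill0(pv, -k))
      den <- den + w[k + 1] * (shift_fill0(vv, k) + shift_fill0(vv, -k))
    }
  }
  fused <- ifelse(valid & den > 0, num / den, NA_real_)
  out <- stream
  out$prob_af <- fused
  out$label[valid] <- ifelse(fused[valid] >= cfg$decision_threshold,
                             "AF", "SINUS")
  out
}

# lag/lead with zero fill (k > 0 pulls from k epochs earlier)
shift_fill0 <- function(x, k) {
  n <- length(x)
  if (k >= n || -k >= n) return(numeric(n))
  if (k > 0) c(numeric(k), x[seq_len(n - k)])
  else if (k < 0) c(x[(1 - k):n], numeric(-k))
  else x
}

#' Minute-by-minute AF yield rate
#'
#' The fraction of the monitoring period for which the algorithm produced a
#' valid AF/non-AF decision, overall and split by the day/night clock
#' windows.
#'
#' @param stream a fused [epoch_stream()].
#' @return A list with elements `overall`, `day`, `night` in `[0, 1]`
#'   (`NA` for an empty window).
#' @export
yield_rate <- function(stream) {
  if (nrow(stream) == 0L) stop("empty stream: yield rate undefined", call. = FALSE)
  valid <- is_valid_epoch(stream)
  day <- is_daytime(stream)
  rate <- function(sel) if (any(sel)) mean(valid[sel]) else NA_real_
  list(overall = mean(valid), day = rate(day), night = rate(!day))
}

#' Run the full fusion stage
#'
#' Convenience composition: quality gate then contextual fusion, returning
#' the fused stream plus its yield rates.
#'
#' @param stream an [epoch_stream()].
#' @param cfg a [fusion_config()].
#' @return A list with `stream` (fused) and `yield` (from [yield_rate()]).
#' @export
fuse_stream <- function(stream, cfg = fusion_config()) {
  gated <- gate_quality(stream, cfg$quality_min)
  fused <- contextual_fuse(gated, cfg)
  list(stream = fused, yield = yield_rate(fused))
}
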