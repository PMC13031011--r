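#' Min-max normalize a cohort feature table
#'
#' Maps every feature to `[0, 1]` by the cohort's min and max so the
#' composite score and its cutoff live on an interpretable unit scale.
#' Zero-variance features are dropped with a warning; missing values are
#' imputed as 0 after normalization (absence of the phenomenon), with the
#' missingness pattern retained.
#'
#' @param features data.frame of numeric feature columns (one row per
#'   subject), e.g. from [extract_feature_table()] minus its id columns.
#' @return A list of class `"feature_normalization"`: `table` (normalized
#'   data.frame), `params` (data.frame `feature`, `min`, `max`), `missing`
#'   (logical matrix of the original missingness).
#' @export
normalize_features <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 2L)
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  rng <- lapply(features, function(x) suppressWarnings(range(x, na.rm = TRUE)))
  all_na <- vapply(features, function(x) all(is.na(x)), logical(1))
  zero_var <- !all_na &
    vapply(rng, function(r) !all(is.finite(r)) || r[1] == r[2], logical(1))
  drop <- all_na | zero_var
  if (any(drop)) {
    warning("dropping constant or all-missing feature(s): ",
            paste(names(features)[drop], collapse = ", "), call. = FALSE)
  }
  features <- features[!drop]
  if (ncol(features) == 0L) stop("no usable features left", call. = FALSE)
  params <- data.frame(
    feature = names(features),
    min = vapply(features, function(x) min(x, na.rm = TRUE), numeric(1)),
    max = vapply(features, function(x) max(x, na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  miss <- is.na(as.matrix(features))
  tab <- apply_normalization(features, params)
  structure(list(table = tab, params = params, missing = miss),
            class = "feature_normalization")
}

#' Apply stored normalization parameters to new feature values
#'
#' @param features data.frame containing (at least) the features named in
#'   `params`.
#' @param params the `params` element of a [normalize_features()] result.
#' @return data.frame of normalized features in `params`' column order;
#'   values outside the training range are clamped to `[0, 1]`, missing
#'   values imputed as 0.
#' @export
apply_normalization <- function(features, params) {
  missing_cols <- setdiff(params$feature, names(features))
  if (length(missing_cols) > 0) {
    stop("features not present: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(params)), function(i) {
    x <- (features[[params$feature[i]]] - params$min[i]) /
      (params$max[i] - params$min[i])
    x[is.na(x)] <- 0
    pmin(1, pmax(0, x))
  })
  names(out) <- params$feature
  as.data.frame(out)
}

#' Derive composite-score weights from per-feature concordance statistics
#'
#' Integrates the three concordance ingredients — correlation strength,
#' explained variance and absolute agreement — into one non-negative weight
#' per feature: the raw weight is the arithmetic mean of `|r|`, `R^2` and
#' `max(ICC, 0)` (a geometric-mean mode is available), and weights are
#' renormalized to sum to 1. Missing ingredients count as 0: a feature the
#' reference cannot corroborate earns no weight.
#'
#' @param stats data.frame with columns `feature`, `r`, `r_squared`, `icc`.
#' @param mode `"arithmetic"` (default) or `"geometric"` mean integration.
#' @return Named numeric vector of weights summing to 1.
#' @export
derive_weights <- function(stats, mode = c("arithmetic", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(all(c("feature", "r", "r_squared", "icc") %in% names(stats)))
  ing <- cbind(abs(stats$r), stats$r_squared, pmax(stats$icc, 0))
  ing[is.na(ing)] <- 0
  raw <- if (mode == "arithmetic") rowMeans(ing)
         else apply(ing, 1, function(v) prod(v)^(1 / 3))
  if (sum(raw) == 0) {
    stop("all concordance statistics are zero: weights degenerate",
         call. = FALSE)
  }
  stats::setNames(raw / sum(raw), stats$feature)
}

#' Composite AF burden score
#'
#' The weighted sum of the normalized 5D features, clamped to `[0, 1]`.
#' Monotone non-decreasing in every feature since weights are non-negative.
#'
#' @param normalized data.frame (or one-row vector) of normalized features.
#' @param weights named weight vector from [derive_weights()] (or supplied
#'   by the user; must be non-negative and named by feature).
#' @return Numeric vector of scores in `[0, 1]`, one per row.
#' @export
composite_score <- function(normalized, weights) {
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  missing_cols <- setdiff(names(weights), names(normalized))
  if (length(missing_cols) > 0) {
    stop("score/feature mismatch: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(normalized[names(weights)])
  pmin(1, pmax(0, as.numeric(m %*% weights)))
}

#' Youden-index optimal cutoff
#'
#' Chooses the score cutoff maximizing Youden's `J = sensitivity +
#' specificity - 1` against a binary clinical event label, classifying
#' positive iff `score >= cutoff`. Candidate cutoffs are the midpoints
#' between consecutive sorted unique scores plus sentinels below and above
#' all scores; ties in `J` break toward the smallest cutoff (the most
#' sensitive rule among the maximizers).
#'
#' @param scores numeric vector.
#' @param events logical (or 0/1) vector of the same length.
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, events) {
  events <- as.logical(events)
  stopifnot(length(scores) == length(events), !anyNA(scores), !anyNA(events))
  n_pos <- sum(events)
  n_neg <- sum(!events)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both event and non-event subjects are required for a cutoff",
         call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- list(j = -Inf)
  for (cut in cand) {
    pos <- scores >= cut
    sens <- sum(pos & events) / n_pos
    spec <- sum(!pos & !events) / n_neg
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec, j = j)
    }
  }
  best
}

#' Fit the composite burden score model on a cohort
#'
#' Ties the scoring pieces together: normalizes the index-device feature
#' table, derives weights from the per-feature concordance statistics
#' against the reference device, scores every subject and selects the
#' Youden-optimal cutoff against the clinical event flags.
#'
#' @param features index-device feature table (numeric columns only are
#'   used; id columns are ignored).
#' @param concordance data.frame with `feature`, `r`, `r_squared`, `icc`
#'   (from [concordance_table()]).
#' @param events logical event flags, one per row of `features`.
#' @param weight_mode passed to [derive_weights()].
#' @return A list of class `"score_model"`: `normalization`, `weights`,
#'   `scores`, `cutoff`, `cutoff_sensitivity`, `cutoff_specificity`, `j`.
#' @export
fit_score_model <- function(features, concordance, events,
                            weight_mode = "arithmetic") {
  id_cols <- intersect(c("subject_id", "device"), names(features))
  norm <- normalize_features(features[setdiff(names(features), id_cols)])
  keep <- concordance$feature %in% norm$params$feature
  w <- derive_weights(concordance[keep, , drop = FALSE], mode = weight_mode)
  scores <- composite_score(norm$table, w)
  yc <- youden_cutoff(scores, events)
  structure(list(normalization = norm$params, weights = w, scores = scores,
                 cutoff = yc$cutoff, cutoff_sensitivity = yc$sensitivity,
                 cutoff_specificity = yc$specificity, j = yc$j),
            class = "score_model")
}
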