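#' Mean absolute error between paired device measurements
#'
#' `MAE = sum(|p_i - g_i|) / n` with `p` the index-device (PPG) values and
#' `g` the reference (Holter ECG) values; pairs with a missing member are
#' removed first.
#'
#' @param p,g numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
mae <- function(p, g) {
  stopifnot(length(p) == length(g))
  ok <- !is.na(p) & !is.na(g)
  if (!any(ok)) stop("no complete pairs", call. = FALSE)
  mean(abs(p[ok] - g[ok]))
}

#' Correlation battery for one paired feature series
#'
#' Pearson (product-moment, t-distributed p), Spearman (Pearson on midranks,
#' large-sample p) and Kendall's tau-b (tie-corrected, normal-approximation
#' p) between index and reference values. When either series has zero
#' variance the correlations are undefined and returned as `NA`.
#'
#' @param p,g numeric vectors of equal length (>= 3 complete pairs for
#'   p-values).
#' @return Named list `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `kendall_tau`, `kendall_p`.
#' @export
correlation_battery <- function(p, g) {
  ok <- !is.na(p) & !is.na(g)
  p <- p[ok]; g <- g[ok]
  out <- list(pearson_r = NA_real_, pearson_p = NA_real_,
              spearman_rho = NA_real_, spearman_p = NA_real_,
              kendall_tau = NA_real_, kendall_p = NA_real_)
  if (length(p) < 3L || stats::sd(p) == 0 || stats::sd(g) == 0) return(out)
  pe <- stats::cor.test(p, g, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(p, g, method = "spearman",
                                         exact = FALSE))
  ke <- suppressWarnings(stats::cor.test(p, g, method = "kendall",
                                         exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       kendall_tau = unname(ke$estimate), kendall_p = ke$p.value)
}

#' Coefficient of determination with bootstrap CI
#'
#' `R^2` of the simple linear regression of the reference values on the
#' index-device values — the proportion of reference variance explained by
#' the wearable, equal to the squared Pearson correlation. The 95% CI is a
#' seeded percentile bootstrap over subjects.
#'
#' @param p,g numeric vectors of equal length.
#' @param ci_bootstrap_n bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return Named list `r_squared`, `ci_lower`, `ci_upper`.
#' @export
r_squared <- function(p, g, ci_bootstrap_n = 2000L, seed = 1L) {
  ok <- !is.na(p) & !is.na(g)
  p <- p[ok]; g <- g[ok]
  if (length(p) < 3L || stats::sd(p) == 0 || stats::sd(g) == 0) {
    return(list(r_squared = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_))
  }
  est <- stats::cor(p, g)^2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(p)
  boots <- vapply(seq_len(ci_bootstrap_n), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(p[idx]) == 0 || stats::sd(g[idx]) == 0) return(NA_real_)
    stats::cor(p[idx], g[idx])^2
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r_squared = est, ci_lower = ci[1], ci_upper = ci[2])
}

#' ICC(A,1): two-way random effects, absolute agreement, single measure
#'
#' The intraclass correlation for absolute agreement between two
#' measurement methods, from the two-way ANOVA decomposition:
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#' with `MS_R` the between-subject, `MS_C` the between-method and `MS_E` the
#' residual mean squares. Unlike Pearson correlation it penalizes fixed
#' between-method bias. The 95% CI uses the F-based interval
#' (Satterthwaite degrees of freedom) for `n >= 10`, and a seeded subject
#' bootstrap for smaller samples. The result carries the conventional
#' banding (`>0.75` excellent, `0.50-0.75` moderate, `<0.50` poor).
#'
#' @param m numeric matrix with `n >= 3` rows (subjects) and `k = 2`
#'   columns (methods); rows with missing values are dropped.
#' @param conf confidence level (default 0.95).
#' @param boot_n,seed bootstrap controls for the small-sample CI.
#' @return Named list `icc`, `ci_lower`, `ci_upper`, `band`.
#' @export
icc_2way_absolute <- function(m, conf = 0.95, boot_n = 2000L, seed = 1L) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  stopifnot(k == 2L)
  na_out <- list(icc = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 band = NA_character_)
  if (n < 3L) return(na_out)
  ms <- icc_mean_squares(m)
  if (ms$ms_r + ms$ms_c + ms$ms_e == 0) return(na_out) # zero total variance
  icc <- icc_from_ms(ms, n, k)
  alpha <- 1 - conf
  if (n >= 10L) {
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * ms$ms_c + b * ms$ms_e)^2 /
      ((a * ms$ms_c)^2 / (k - 1) + (b * ms$ms_e)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$ms_r - f_l * ms$ms_e) /
      (f_l * (k * ms$ms_c + (k * n - k - n) * ms$ms_e) + n * ms$ms_r)
    upper <- n * (f_u * ms$ms_r - ms$ms_e) /
      (k * ms$ms_c + (k * n - k - n) * ms$ms_e + n * f_u * ms$ms_r)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    boots <- vapply(seq_len(boot_n), function(i) {
      mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
      msb <- icc_mean_squares(mb)
      if (msb$ms_r + msb$ms_c + msb$ms_e == 0) return(NA_real_)
      icc_from_ms(msb, n, k)
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
    lower <- ci[1]; upper <- ci[2]
  }
  band <- if (icc > 0.75) "excellent" else if (icc >= 0.50) "moderate" else "poor"
  list(icc = icc, ci_lower = max(-1, lower), ci_upper = min(1, upper),
       band = band)
}

icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  list(ms_r = ss_r / (n - 1), ms_c = ss_c / (k - 1),
       ms_e = ss_e / ((n - 1) * (k - 1)))
}

icc_from_ms <- function(ms, n, k) {
  (ms$ms_r - ms$ms_e) /
    (ms$ms_r + (k - 1) * ms$ms_e + (k / n) * (ms$ms_c - ms$ms_e))
}

#' Wilson score interval for a binomial proportion
#'
#' The 95% (by default) Wilson interval without continuity correction:
#' center `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Always within `[0, 1]`;
#' the lower bound is exactly 0 when `k = 0`.
#'
#' @param k successes, `n` trials.
#' @param conf confidence level.
#' @return Named list `estimate`, `ci_lower`, `ci_upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the bounds are exactly 0 / 1 at the boundary counts; avoid float residue
  lower <- if (k == 0) 0 else max(0, center - half)
  upper <- if (k == n) 1 else min(1, center + half)
  list(estimate = p, ci_lower = lower, ci_upper = upper)
}

#' Per-epoch confusion metrics with Wilson intervals
#'
#' Sensitivity, specificity and accuracy of the index-device AF labels
#' against the reference labels on timestamp-aligned epochs. Epochs invalid
#' on either device are excluded pairwise (only valid classification output
#' is scored). Each metric carries its 95% Wilson interval; a metric whose
#' class is absent is `NA`.
#'
#' @param pred,truth character label vectors (`"AF"`/`"SINUS"`/`"INVALID"`)
#'   aligned 1:1, or two [epoch_stream()]s with identical timestamps.
#' @return Named list of lists `sensitivity`, `specificity`, `accuracy`
#'   (each `estimate`, `ci_lower`, `ci_upper`) plus counts `n_pairs`, `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred, truth) {
  if (inherits(pred, "epoch_stream")) {
    if (!identical(as.numeric(pred$start_time), as.numeric(truth$start_time))) {
      stop("streams are not timestamp-aligned", call. = FALSE)
    }
    pred <- pred$label; truth <- truth$label
  }
  stopifnot(length(pred) == length(truth))
  ok <- pred != "INVALID" & truth != "INVALID"
  pred <- pred[ok] == "AF"; truth <- truth[ok] == "AF"
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  met <- function(k, n) {
    if (n == 0) list(estimate = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_)
    else wilson_ci(k, n)
  }
  list(sensitivity = met(tp, tp + fn),
       specificity = met(tn, tn + fp),
       accuracy = met(tp + tn, length(pred)),
       n_pairs = length(pred), tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC and precision-recall evaluation
#'
#' ROC curve by threshold sweep over the unique scores (tied scores move
#' together), AUC by the trapezoid rule, and the precision-recall curve
#' with step-wise average precision. The AUC CI is a seeded percentile
#' bootstrap over subjects.
#'
#' @param scores numeric vector.
#' @param truth logical (or 0/1) vector.
#' @param boot_n bootstrap replicates for the AUC CI (0 to skip).
#' @param seed bootstrap seed.
#' @return A list: `roc_auc`, `auc_ci_lower`, `auc_ci_upper`, `pr_auc`
#'   (average precision), `roc` (data.frame `fpr`, `tpr`, `threshold`),
#'   `pr` (data.frame `recall`, `precision`).
#' @export
roc_pr <- function(scores, truth, boot_n = 2000L, seed = 1L) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes are required for ROC/PR evaluation", call. = FALSE)
  }
  curves <- roc_points(scores, truth)
  auc <- trapezoid_auc(curves$roc$fpr, curves$roc$tpr)

  ci <- c(NA_real_, NA_real_)
  if (boot_n > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n <- length(scores)
    boots <- vapply(seq_len(boot_n), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(truth[idx]) || !any(truth[idx])) return(NA_real_)
      r <- roc_points(scores[idx], truth[idx])$roc
      trapezoid_auc(r$fpr, r$tpr)
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(roc_auc = auc, auc_ci_lower = ci[1], auc_ci_upper = ci[2],
       pr_auc = curves$pr_auc, roc = curves$roc, pr = curves$pr)
}

roc_points <- function(scores, truth) {
  n_pos <- sum(truth); n_neg <- sum(!truth)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # collapse tied scores: all equal scores cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                    threshold = c(Inf, thr))
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # step-wise average precision: sum precision * increment in recall
  pr_auc <- sum(precision * diff(c(0, recall)))
  list(roc = roc, pr = data.frame(recall = recall, precision = precision),
       pr_auc = pr_auc)
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Kruskal-Wallis H test across clinical categories
#'
#' Rank-based test of whether a progression feature's distribution differs
#' across groups (EHRA class, risk profile, treatment), with midranks and
#' tie correction; p-value from the chi-square approximation with
#' `groups - 1` degrees of freedom. When all values are identical the test
#' is degenerate and returns `H = 0`, `p = 1`.
#'
#' @param values numeric vector, or a list of numeric group vectors.
#' @param groups grouping factor (ignored when `values` is a list).
#' @return Named list `h`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  if (length(unique(values)) == 1L) {
    return(list(h = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Per-feature concordance table for paired device feature tables
#'
#' Runs the MAE, correlation battery, R-squared and ICC(A,1) for each
#' feature measured by both devices on the same subjects — the agreement
#' table of the wearable-vs-Holter comparison.
#'
#' @param fi,fr index-device and reference-device feature tables carrying a
#'   `subject_id` column; subjects present in only one table are skipped
#'   with a warning.
#' @param features feature columns to compare (default: all shared numeric
#'   columns).
#' @param seed seed for the bootstrap CIs.
#' @return data.frame, one row per feature: `feature`, `n`, `mae`, `r`,
#'   `r_p`, `spearman_rho`, `spearman_p`, `kendall_tau`, `kendall_p`,
#'   `r_squared`, `r2_ci_lower`, `r2_ci_upper`, `icc`, `icc_ci_lower`,
#'   `icc_ci_upper`, `icc_band`.
#' @export
concordance_table <- function(fi, fr, features = NULL, seed = 1L) {
  stopifnot("subject_id" %in% names(fi), "subject_id" %in% names(fr))
  common <- intersect(fi$subject_id, fr$subject_id)
  dropped <- setdiff(union(fi$subject_id, fr$subject_id), common)
  if (length(dropped) > 0) {
    warning("skipping unmatched subject(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  fi <- fi[match(common, fi$subject_id), , drop = FALSE]
  fr <- fr[match(common, fr$subject_id), , drop = FALSE]
  if (is.null(features)) {
    shared <- intersect(names(fi), names(fr))
    features <- shared[vapply(fi[shared], is.numeric, logical(1))]
  }
  rows <- lapply(features, function(f) {
    p <- fi[[f]]; g <- fr[[f]]
    ok <- !is.na(p) & !is.na(g)
    n <- sum(ok)
    cb <- correlation_battery(p, g)
    r2 <- r_squared(p, g, seed = seed)
    icc <- if (n >= 3L) icc_2way_absolute(cbind(p[ok], g[ok]), seed = seed)
           else list(icc = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_, band = NA_character_)
    data.frame(feature = f, n = n,
               mae = if (n >= 1) mae(p, g) else NA_real_,
               r = cb$pearson_r, r_p = cb$pearson_p,
               spearman_rho = cb$spearman_rho, spearman_p = cb$spearman_p,
               kendall_tau = cb$kendall_tau, kendall_p = cb$kendall_p,
               r_squared = r2$r_squared, r2_ci_lower = r2$ci_lower,
               r2_ci_upper = r2$ci_upper,
               icc = icc$icc, icc_ci_lower = icc$ci_lower,
               icc_ci_upper = icc$ci_upper, icc_band = icc$band,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full concordance report for a paired cohort
#'
#' Assembles the complete agreement picture: the per-feature concordance
#' table, pooled per-epoch confusion metrics of the index labels against the
#' reference labels, and ROC/PR evaluation of the fused index probabilities
#' against the reference labels.
#'
#' @param index,reference lists of fused [epoch_stream()]s keyed by subject.
#' @param fi,fr matching feature tables (default: extracted here).
#' @param seed bootstrap seed.
#' @return A list of class `"concordance_report"`: `features` (the table),
#'   `epoch` (confusion metrics), `roc` (ROC/PR results), `n_subjects`.
#' @export
build_report <- function(index, reference, fi = NULL, fr = NULL, seed = 1L) {
  stopifnot(length(index) == length(reference))
  if (is.null(fi)) fi <- extract_feature_table(index)
  if (is.null(fr)) fr <- extract_feature_table(reference)
  tab <- concordance_table(fi, fr, seed = seed)

  pred <- unlist(lapply(index, `[[`, "label"), use.names = FALSE)
  truth <- unlist(lapply(reference, `[[`, "label"), use.names = FALSE)
  epoch <- confusion_metrics(pred, truth)

  prob <- unlist(lapply(index, `[[`, "prob_af"), use.names = FALSE)
  ok <- !is.na(prob) & truth != "INVALID"
  roc <- if (any(truth[ok] == "AF") && any(truth[ok] != "AF")) {
    roc_pr(prob[ok], truth[ok] == "AF", boot_n = 200L, seed = seed)
  } else NULL
  structure(list(features = tab, epoch = epoch, roc = roc,
                 n_subjects = length(index)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d subjects, %d epoch pairs\n",
              x$n_subjects, x$epoch$n_pairs))
  if (!is.na(x$epoch$sensitivity$estimate)) {
    cat(sprintf("  per-epoch sens %.3f spec %.3f acc %.3f\n",
                x$epoch$sensitivity$estimate, x$epoch$specificity$estimate,
                x$epoch$accuracy$estimate))
  }
  if (!is.null(x$roc)) {
    cat(sprintf("  ROC-AUC %.3f, PR-AUC %.3f\n", x$roc$roc_auc, x$roc$pr_auc))
  }
  print(x$features[, c("feature", "n", "mae", "r", "r_squared", "icc")],
        digits = 3)
  invisible(x)
}
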