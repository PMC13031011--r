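#' Read an epoch-stream CSV
#'
#' Reads the package's epoch-stream dialect: header
#' `subject_id,device,start_time,label,prob_af,pulse_bpm,quality`, ISO-8601
#' timestamps, labels in `AF`/`SINUS`/`INVALID`, empty cells allowed for
#' `prob_af`/`pulse_bpm`. Timestamp gaps are filled with `INVALID` epochs so
#' the stream has uniform 1-minute spacing (every burden ratio needs a
#' well-defined total-time denominator). `write_epoch_csv()` followed by
#' `read_epoch_csv()` is the identity.
#'
#' @param path CSV file path.
#' @param tz timezone in which clock times are interpreted (default UTC).
#' @return An [epoch_stream()].
#' @export
read_epoch_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  expected <- c("subject_id", "device", "start_time", "label",
                "prob_af", "pulse_bpm", "quality")
  if (!identical(names(df), expected)) {
    stop("bad header in ", path, ": expected ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  bad_lab <- which(!df$label %in% c("AF", "SINUS", "INVALID"))
  if (length(bad_lab) > 0) {
    stop("invalid label '", df$label[bad_lab[1]], "' at line ",
         bad_lab[1] + 1L, " of ", path, call. = FALSE)
  }
  tt <- as.POSIXct(df$start_time, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tt)) {
    stop("unparseable start_time at line ", which(is.na(tt))[1] + 1L,
         " of ", path, call. = FALSE)
  }
  if (any(diff(as.numeric(tt)) <= 0)) {
    stop("start_time not strictly increasing at line ",
         which(diff(as.numeric(tt)) <= 0)[1] + 2L, " of ", path,
         call. = FALSE)
  }
  # gap-fill to uniform 1-minute spacing
  full <- seq(tt[1], tt[length(tt)], by = 60)
  idx <- match(as.numeric(full), as.numeric(tt))
  present <- !is.na(idx)
  label <- ifelse(present, df$label[idx], "INVALID")
  prob <- ifelse(present, df$prob_af[idx], NA_real_)
  pulse <- ifelse(present, df$pulse_bpm[idx], NA_real_)
  qual <- ifelse(present, df$quality[idx], 0)
  epoch_stream(full, label, prob, pulse, qual,
               subject_id = df$subject_id[1],
               device = df$device[1])
}

#' Write an epoch stream to CSV
#'
#' Emits the dialect read by [read_epoch_csv()] bit-exactly: stable column
#' order, ISO-8601 timestamps, '.' decimal, empty cells for missing
#' `prob_af`/`pulse_bpm`.
#'
#' @param stream an [epoch_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(stream, path) {
  df <- data.frame(
    subject_id = attr(stream, "subject_id"),
    device = attr(stream, "device"),
    start_time = format(stream$start_time, "%Y-%m-%dT%H:%M:%S"),
    label = stream$label,
    prob_af = stream$prob_af,
    pulse_bpm = stream$pulse_bpm,
    quality = stream$quality)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate, fuse, extract features, fit the composite score and build the
#' concordance report in one seeded, deterministic call — the programmatic
#' equivalent of running every pipeline stage in order. When `out_dir` is
#' given, the feature tables, concordance table, score model and a manifest
#' (seed, parameters, artifact names) are written there as CSV/JSON.
#'
#' @param params a [sim_params()] object.
#' @param seed integer master seed for every stochastic stage.
#' @param cfg a [fusion_config()].
#' @param out_dir optional output directory for artifacts.
#' @return A list of class `"af_pipeline"`: `cohort`, `fused` (list of
#'   fused index streams), `yield` (per-subject yield data.frame),
#'   `features_index`, `features_reference`, `report`
#'   (a `"concordance_report"`), `score` (a `"score_model"`), `clinical`.
#' @export
run_pipeline <- function(params = sim_params(), seed = 1L,
                         cfg = fusion_config(), out_dir = NULL) {
  cohort <- simulate_cohort(params, seed)
  fused <- lapply(cohort$index, function(s) fuse_stream(s, cfg)$stream)
  yields <- lapply(fused, yield_rate)
  yield <- data.frame(subject_id = names(fused),
                      overall = vapply(yields, `[[`, numeric(1), "overall"),
                      day = vapply(yields, `[[`, numeric(1), "day"),
                      night = vapply(yields, `[[`, numeric(1), "night"),
                      row.names = NULL)
  fi <- extract_feature_table(fused)
  fr <- extract_feature_table(cohort$reference)
  report <- build_report(fused, cohort$reference, fi, fr, seed = seed)
  score <- fit_score_model(fi, report$features, cohort$clinical$event_flag)
  res <- structure(list(cohort = cohort, fused = fused, yield = yield,
                        features_index = fi, features_reference = fr,
                        report = report, score = score,
                        clinical = cohort$clinical),
                   class = "af_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir, seed)
  res
}

write_pipeline_artifacts <- function(res, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    features_index = file.path(out_dir, "features_index.csv"),
    features_reference = file.path(out_dir, "features_reference.csv"),
    concordance = file.path(out_dir, "concordance.csv"),
    yield = file.path(out_dir, "yield.csv"),
    clinical = file.path(out_dir, "clinical_labels.csv"),
    score_model = file.path(out_dir, "score_model.json"))
  utils::write.csv(res$features_index, paths$features_index, row.names = FALSE)
  utils::write.csv(res$features_reference, paths$features_reference,
                   row.names = FALSE)
  utils::write.csv(res$report$features, paths$concordance, row.names = FALSE)
  utils::write.csv(res$yield, paths$yield, row.names = FALSE)
  utils::write.csv(res$clinical, paths$clinical, row.names = FALSE)
  sm <- res$score
  jsonlite::write_json(
    list(normalization = sm$normalization,
         weights = as.list(sm$weights),
         cutoff = sm$cutoff,
         cutoff_sensitivity = sm$cutoff_sensitivity,
         cutoff_specificity = sm$cutoff_specificity),
    paths$score_model, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "afburden",
         version = as.character(utils::packageVersion("afburden")),
         seed = seed,
         n_subjects = res$cohort$params$n_subjects,
         artifacts = lapply(paths, basename)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(paths)
}
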