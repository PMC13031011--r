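# independent AF-density oracle: fine Riemann sum over the piecewise-linear
# AF accumulation curve, no shared code with af_density()
oracle_density <- function(labels, steps_per_epoch = 400) {
  lab <- strsplit(labels, "")[[1]]
  af <- lab[lab != "I"] == "A"
  n <- length(af)
  n_af <- sum(af)
  b <- n_af / n
  if (n_af == 0 || n_af == n) return(0)
  u_step <- 1 / (n * steps_per_epoch)
  cum <- 0
  total <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(steps_per_epoch)) {
      u <- ((j - 1) * steps_per_epoch + k - 0.5) * u_step
      C <- (cum + af[j] * (k - 0.5) / steps_per_epoch) / n_af
      total <- total + abs(C - u) * u_step
    }
    cum <- cum + af[j]
  }
  total / ((1 - b) / 2)
}

test_that("number features match hand counts", {
  # one 10-min episode in 100 valid minutes
  s <- make_stream(paste0(strrep("A", 10), strrep("S", 90)))
  acct <- time_accounting(s)
  ep <- extract_episodes(s)
  expect_equal(number_features(ep, acct),
               list(af_epoch_ratio = 0.10, episodes_ge6_ratio = 0.01,
                    episodes_ge1h_ratio = 0.0))

  # one continuous 120-min episode qualifies in both strata
  s <- make_stream(strrep("A", 120))
  nf <- number_features(extract_episodes(s), time_accounting(s))
  expect_equal(nf, list(af_epoch_ratio = 1.0, episodes_ge6_ratio = 1 / 120,
                        episodes_ge1h_ratio = 1 / 120))

  # zero AF
  s <- make_stream(strrep("S", 50))
  nf <- number_features(extract_episodes(s), time_accounting(s))
  expect_equal(unlist(nf, use.names = FALSE), c(0, 0, 0))

  # zero valid time: features are missing, not zero
  s <- make_stream("III")
  nf <- number_features(extract_episodes(s), time_accounting(s))
  expect_true(all(is.na(unlist(nf))))
})

test_that("duration features match hand counts and assign strata strictly", {
  s <- make_stream(paste0(strrep("A", 10), strrep("S", 90)))
  df <- duration_features(extract_episodes(s), time_accounting(s))
  expect_equal(df, list(burden_all = 0.10, burden_ge6 = 0.10,
                        burden_ge1h = 0.0))

  # continuous AF over a 2-hour stream saturates every stratum
  s <- make_stream(strrep("A", 120))
  df <- duration_features(extract_episodes(s), time_accounting(s))
  expect_equal(unlist(df, use.names = FALSE), c(1, 1, 1))

  # 5-min + 61-min episodes in 660 valid minutes: the 5-min episode counts
  # toward overall burden only
  s <- make_stream(paste0(strrep("A", 5), strrep("S", 20), strrep("A", 61),
                          strrep("S", 574)))
  df <- duration_features(extract_episodes(s), time_accounting(s))
  expect_equal(df$burden_all, 66 / 660)
  expect_equal(df$burden_ge6, 61 / 660)
  expect_equal(df$burden_ge1h, 61 / 660)
})

test_that("monotonicity and ratio bounds hold on random streams", {
  set.seed(5)
  for (rep in 1:300) {
    s <- make_stream(random_labels(sample(10:200, 1)))
    if (time_accounting(s)$n_valid == 0) next
    ep <- extract_episodes(s, bridging_gap_max = sample(0:3, 1))
    acct <- time_accounting(s)
    nf <- number_features(ep, acct)
    df <- duration_features(ep, acct)
    expect_gte(df$burden_all, df$burden_ge6)
    expect_gte(df$burden_ge6, df$burden_ge1h)
    expect_gte(nf$episodes_ge6_ratio, nf$episodes_ge1h_ratio)
    expect_true(all(unlist(df) >= 0 & unlist(df) <= 1))
  }
})

test_that("af_density is 1 for single-block AF, vanishes for interleaving, matches the oracle", {
  # one AF block at the start, b = 0.5
  expect_equal(af_density(make_stream(paste0(strrep("A", 30), strrep("S", 30)))),
               1.0)
  # one block at the end
  expect_equal(af_density(make_stream(paste0(strrep("S", 30), strrep("A", 30)))),
               1.0)
  # single block, other burdens
  expect_equal(af_density(make_stream(paste0(strrep("A", 10), strrep("S", 90)))),
               1.0, tolerance = 1e-12)

  # perfect interleaving: density bounded by 1/(number of episodes), -> 0
  for (n in c(40, 100, 200)) {
    s <- make_stream(strrep("AS", n / 2))
    d <- af_density(s)
    expect_lte(d, 1 / (n / 2) + 1e-12)
    expect_gte(d, 0)
  }

  # degenerate burdens are defined 0
  expect_equal(af_density(make_stream(strrep("A", 20))), 0)
  expect_equal(af_density(make_stream(strrep("S", 20))), 0)

  # two-block case against the independent Riemann oracle
  lab <- paste0(strrep("A", 15), strrep("S", 15), strrep("A", 15),
                strrep("S", 75))
  expect_equal(af_density(make_stream(lab)), oracle_density(lab),
               tolerance = 1e-3)

  # random streams against the oracle
  set.seed(13)
  for (rep in 1:10) {
    lab <- random_labels(60)
    s <- make_stream(lab)
    v <- sum(strsplit(lab, "")[[1]] != "I")
    if (v == 0) next
    expect_equal(af_density(s), oracle_density(lab), tolerance = 1e-3)
    expect_gte(af_density(s), 0)
    expect_lte(af_density(s), 1)
  }
})

test_that("af_density and burden are invariant under stream reversal", {
  set.seed(17)
  for (rep in 1:20) {
    lab <- random_labels(120)
    rev_lab <- paste(rev(strsplit(lab, "")[[1]]), collapse = "")
    s <- make_stream(lab); r <- make_stream(rev_lab)
    if (time_accounting(s)$n_valid == 0) next
    expect_equal(af_density(s), af_density(r), tolerance = 1e-9)
    expect_equal(duration_features(extract_episodes(s, 0), time_accounting(s))$burden_all,
                 duration_features(extract_episodes(r, 0), time_accounting(r))$burden_all)
  }
})

test_that("circadian features match their hand-derived cases", {
  # onsets at 06:00 and 12:00: two-point CV of onset
  s <- epoch_stream(as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:1439),
                    expand_labels(c(rep("S", 360), "A", rep("S", 359), "A", rep("S", 719))))
  ep <- extract_episodes(s, bridging_gap_max = 0)
  cf <- circadian_features(s, ep)
  expect_equal(nrow(ep), 2L)
  expect_equal(cf$cv_onset, sqrt(2 * 180^2) / 540, tolerance = 1e-10)

  # arv on constructed hourly burdens [0.2, 0.4, 0.1] -> 0.25
  lab <- c(rep(c("A", rep("S", 4)), 12),          # hour 0: burden 0.2
           rep(c("A", "A", rep("S", 3)), 12),     # hour 1: burden 0.4
           rep(c("A", rep("S", 9)), 6))           # hour 2: burden 0.1
  s <- make_stream(paste(lab, collapse = ""))
  cf <- circadian_features(s, extract_episodes(s, 0))
  expect_equal(cf$arv, 0.25)

  # full swings [0, 1, 0] -> arv 1
  s <- make_stream(paste0(strrep("S", 60), strrep("A", 60), strrep("S", 60)))
  cf <- circadian_features(s, extract_episodes(s, 0))
  expect_equal(cf$arv, 1.0)
})

test_that("vom is a signed symmetric day/night contrast", {
  # equal day and night AF frequency -> 0
  lab <- rep("S", 1440)
  lab[seq(1, 1440, by = 10)] <- "A"   # AF every 10th minute all day
  s <- epoch_stream(as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:1439), expand_labels(lab))
  cf <- circadian_features(s, extract_episodes(s, 0))
  expect_equal(cf$vom, 0, tolerance = 1e-12)

  # AF only at night -> -1; only in the day -> +1; no AF -> 0
  night_only <- rep("S", 1440); night_only[1:120] <- "A" # 00:00-02:00
  s <- epoch_stream(as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:1439), expand_labels(night_only))
  expect_equal(circadian_features(s, extract_episodes(s, 0))$vom, -1)

  day_only <- rep("S", 1440); day_only[600:700] <- "A"  # ~10:00
  s <- epoch_stream(as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:1439), expand_labels(day_only))
  expect_equal(circadian_features(s, extract_episodes(s, 0))$vom, 1)

  s <- make_stream(strrep("S", 100))
  expect_equal(circadian_features(s, extract_episodes(s, 0))$vom, 0)
})

test_that("circadian features are invariant to epoch order within hours", {
  set.seed(23)
  lab <- sample(c("A", "S", "I"), 1440, replace = TRUE, prob = c(0.2, 0.7, 0.1))
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  s1 <- epoch_stream(t0 + 60 * (0:1439), expand_labels(lab))
  perm <- unlist(lapply(0:23, function(h) h * 60 + sample(60)))
  s2 <- epoch_stream(t0 + 60 * (0:1439), expand_labels(lab[perm]))
  f1 <- circadian_features(s1, extract_episodes(s1, 0))
  f2 <- circadian_features(s2, extract_episodes(s2, 0))
  # all hour-resolution metrics are permutation-invariant (episode-onset CV
  # is minute-resolved, so it is exempt)
  for (nm in c("vom", "af_variability", "day_af_variability",
               "night_af_variability", "arv")) {
    expect_equal(f1[[nm]], f2[[nm]], info = nm)
  }
})

test_that("tachycardia features use the strict 120 bpm threshold and coincide", {
  s <- make_stream(strrep("S", 30), pulse_bpm = 130)
  expect_equal(tachycardia_features(s),
               list(tachy_duration_ratio = 1.0, tachy_epoch_ratio = 1.0))

  s <- make_stream(strrep("S", 30), pulse_bpm = 120) # exactly at threshold
  expect_equal(tachycardia_features(s)$tachy_duration_ratio, 0)

  pulse <- c(rep(150, 12), rep(80, 228))
  s <- make_stream(strrep("S", 240), pulse_bpm = pulse)
  tf <- tachycardia_features(s)
  expect_equal(tf$tachy_duration_ratio, 0.05)
  expect_equal(tf$tachy_epoch_ratio, tf$tachy_duration_ratio)

  # identity of the two ratios on random pulse streams (1-minute epochs)
  set.seed(29)
  for (rep in 1:20) {
    s <- make_stream(random_labels(100), pulse_bpm = runif(100, 60, 160))
    tf <- tachycardia_features(s)
    expect_identical(tf$tachy_duration_ratio, tf$tachy_epoch_ratio)
  }

  s <- make_stream("SSS", pulse_bpm = NA_real_)
  expect_true(is.na(tachycardia_features(s)$tachy_duration_ratio))
})

test_that("extract_features composes the dimensions and propagates missingness", {
  p <- sim_params(n_subjects = 2, base_onset_rate = 0.3)
  tr <- simulate_subject(p, 1, seed = 31)$stream
  fv <- extract_features(tr)
  dims <- feature_dimensions()
  expect_true(all(unlist(dims) %in% names(fv)))
  # noiseless truth: burden equals the label fraction exactly
  expect_equal(fv$burden_all, mean(tr$label == "AF"))

  # zero-valid stream: all features missing
  fv0 <- extract_features(make_stream("IIII"))
  expect_true(all(is.na(unlist(fv0[unlist(dims)]))))

  # zero-AF stream: number/duration/aggregation zero
  fvs <- extract_features(make_stream(strrep("S", 200)))
  expect_equal(unlist(fvs[c(dims$number, dims$duration, dims$aggregation)],
                      use.names = FALSE),
               rep(0, 7))
})
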