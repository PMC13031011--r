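# Test builders and independent oracles. Single-letter label shorthand:
# A = AF, S = SINUS, I = INVALID.

t_origin <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

# stream from a compact label string, starting at `start` (POSIXct)
make_stream <- function(labels, start = t_origin, prob_af = NA_real_,
                        pulse_bpm = NA_real_, quality = 1, ...) {
  lab <- c(A = "AF", S = "SINUS", I = "INVALID")[strsplit(labels, "")[[1]]]
  epoch_stream(start + 60 * (seq_along(lab) - 1), unname(lab),
               prob_af = prob_af, pulse_bpm = pulse_bpm, quality = quality,
               ...)
}

# independent episode oracle: scan runs of A, merging across runs separated
# by <= gap consecutive I's (never across an S); written as a direct
# character-level scan, no shared code with extract_episodes()
oracle_episodes <- function(labels, gap) {
  ch <- strsplit(labels, "")[[1]]
  eps <- list()
  cur_start <- NA
  cur_end <- NA
  i_run <- 0
  for (i in seq_along(ch)) {
    if (ch[i] == "A") {
      if (is.na(cur_start)) cur_start <- i
      else if (i_run > gap) { # gap too long: close previous episode
        eps[[length(eps) + 1]] <- c(cur_start, cur_end)
        cur_start <- i
      }
      cur_end <- i
      i_run <- 0
    } else if (ch[i] == "I") {
      i_run <- i_run + 1
    } else { # S terminates unconditionally
      if (!is.na(cur_start)) {
        eps[[length(eps) + 1]] <- c(cur_start, cur_end)
        cur_start <- NA
      }
      i_run <- 0
    }
  }
  if (!is.na(cur_start)) eps[[length(eps) + 1]] <- c(cur_start, cur_end)
  data.frame(
    onset_idx = vapply(eps, `[`, numeric(1), 1),
    duration_min = vapply(eps, function(e) e[2] - e[1] + 1, numeric(1)),
    n_af = vapply(eps, function(e) {
      sum(ch[e[1]:e[2]] == "A")
    }, numeric(1)))
}

# expand a vector of single-letter labels to full rhythm labels
expand_labels <- function(x) {
  unname(c(A = "AF", S = "SINUS", I = "INVALID")[x])
}

# all label strings of a given length over {A, S, I}
all_label_strings <- function(len) {
  apply(expand.grid(rep(list(c("A", "S", "I")), len)), 1, paste, collapse = "")
}

# random label string under a fixed-seeded RNG (caller sets the seed)
random_labels <- function(len, p = c(0.3, 0.5, 0.2)) {
  paste(sample(c("A", "S", "I"), len, replace = TRUE, prob = p), collapse = "")
}
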