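# Independent brute-force oracles used across tests. Deliberately written as
# plain loops, sharing no code with the package internals.

# scan for maximal runs of valid samples strictly below a threshold lasting
# at least min_dur seconds
oracle_runs <- function(x, valid, rate, threshold, min_dur) {
  n <- length(x)
  onsets <- durs <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (valid[i] && !is.na(x[i]) && x[i] < threshold) {
      j <- i
      while (j < n && valid[j + 1L] && !is.na(x[j + 1L]) &&
             x[j + 1L] < threshold) {
        j <- j + 1L
      }
      len <- (j - i + 1L) / rate
      if (len >= min_dur) {
        onsets <- c(onsets, (i - 1L) / rate)
        durs <- c(durs, len)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(onset = onsets, duration = durs)
}

# pause classification from a breath-onset list, from first principles
oracle_pauses <- function(onsets, short_min = 3, short_max = 5) {
  med <- median(diff(onsets))
  out <- data.frame(onset = numeric(), duration = numeric(),
                    type = character())
  for (k in seq_len(length(onsets) - 1L)) {
    d <- (onsets[k + 1L] - onsets[k]) - med
    if (d > short_max) {
      out <- rbind(out, data.frame(onset = onsets[k] + med, duration = d,
                                   type = "pause_long"))
    } else if (d > short_min) {
      out <- rbind(out, data.frame(onset = onsets[k] + med, duration = d,
                                   type = "pause_short"))
    }
  }
  out
}

# random step-wise test signal with occasional sub-threshold excursions and
# invalid patches
random_level_signal <- function(n, rate, base, dip_levels, dip_p = 0.02) {
  x <- rep(base, n)
  k <- 1L
  while (k <= n) {
    if (runif(1) < dip_p) {
      len <- sample.int(round(8 * rate), 1L)
      lev <- sample(dip_levels, 1L)
      x[k:min(n, k + len - 1L)] <- lev + runif(1, -1, 1)
      k <- k + len
    } else {
      k <- k + 1L
    }
  }
  valid <- runif(n) > 0.01
  list(values = x, valid = valid, rate = rate)
}

# small noise-free synthetic recording shared by several tests
noise_free_params <- function(duration_h = 2, seed = 21, ...) {
  sim_params(duration_h = duration_h, seed = seed,
             noise_sd = c(resp = 0, spo2 = 0, hr = 0),
             breath_jitter_sd = 0, breath_amp_jitter = 0, ...)
}

short_schedule <- function(duration_h, order = "off_first") {
  stim_schedule(order, block_hours = duration_h / 4, n_blocks = 4)
}
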