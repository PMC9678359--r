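# Shared builders for desk-scale synthetic inputs.

# Small cohort: few channels, full 60-trial-per-type design so the n = 60
# reference thresholds apply.
small_cohort <- function(n_patients = 1, channels = 4, trials_per_type = 60,
                         movies = 30) {
  cohort_spec(n_patients = n_patients,
              channels_per_patient = rep(channels, n_patients),
              n_trials_per_type = trials_per_type,
              n_movies_per_type = movies)
}

# Reduced-resolution broadband power for an epoch set: 18 in-band
# frequencies, 10 ms steps, output restricted to baseline + [0.9, 2] s.
quick_bbp <- function(es, extra_times = NULL) {
  wt <- sort(unique(c(seq(-1, -0.0025, 0.01), seq(0.9, 2, 0.01),
                      extra_times)))
  tf <- baseline_percent_change(
    tfr_hanning(es, freqs = seq(20, 190, 10), out_times = wt))
  list(bbp = band_power(tf), times = tf$times)
}

# Direct synthetic coding maps (channels x freqs x times): smooth null
# fields from correlating autocorrelated trial noise with ratings, plus an
# optional injected effect added to the r-scale inside a window.
null_coding_maps <- function(n_ch = 10, n_f = 12, n_t = 60, n_trials = 24,
                             smooth = 5) {
  ratings <- sample(1:4, n_trials, TRUE)
  maps <- array(0, c(n_ch, n_f, n_t))
  ker <- rep(1 / smooth, smooth)
  for (ch in seq_len(n_ch)) {
    pw <- matrix(rnorm(n_trials * (n_t + smooth)), n_trials)
    pw <- t(apply(pw, 1, function(v) stats::filter(v, ker, sides = 1)))
    pw <- pw[, (smooth + 1):(n_t + smooth)]
    for (f in seq_len(n_f)) {
      jit <- pw + matrix(rnorm(n_trials * n_t, sd = 0.5), n_trials)
      maps[ch, f, ] <- suppressWarnings(
        as.vector(cor(apply(jit, 2, rank), rank(ratings))))
    }
  }
  maps
}
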