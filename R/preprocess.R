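# Preprocessing of depth-electrode recordings: bipolar re-referencing,
# epoching/detrending, Hanning-taper time-frequency decomposition,
# baseline normalization, outlier-point rejection and band averaging.

#' Construct an epoched LFP container
#'
#' @param data Array `trials x channels x samples` (microvolts).
#' @param fs Sampling rate in Hz (400 after decimation).
#' @param t_start Time of the first sample relative to movie onset (s).
#' @param trial_meta Data frame with one row per trial (stimulus type,
#'   rating, movie id, ...). Optional.
#' @param channel_meta Data frame with one row per channel (patient, MNI
#'   coordinates, insula flag, ...). Optional.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t_start = -1, trial_meta = NULL,
                      channel_meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (!is.null(trial_meta)) stopifnot(nrow(trial_meta) == dim(data)[1])
  if (!is.null(channel_meta)) stopifnot(nrow(channel_meta) == dim(data)[2])
  structure(list(
    data = data, fs = fs,
    times = t_start + (seq_len(dim(data)[3]) - 1) / fs,
    trial_meta = trial_meta, channel_meta = channel_meta
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] s\n",
              d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Bipolar re-referencing of depth-electrode contacts
#'
#' Subtracts adjacent contacts along each electrode shaft, yielding one
#' bipolar channel per adjacent pair; the bipolar channel's coordinate is
#' the midpoint of its two contacts. Shafts with fewer than two contacts
#' are skipped with a warning.
#'
#' @param raw Matrix `contacts x samples`, contacts ordered along shafts.
#' @param shaft Factor/vector giving the shaft of each contact.
#' @param contact_meta Optional data frame per contact; numeric columns
#'   named `x`, `y`, `z` (MNI mm) are averaged into midpoints, other
#'   columns are taken from the first contact of the pair.
#' @return List with `data` (`channels x samples`) and `channel_meta`.
#' @export
bipolar_rereference <- function(raw, shaft, contact_meta = NULL) {
  stopifnot(is.matrix(raw), length(shaft) == nrow(raw))
  chans <- list(); metas <- list()
  for (s in unique(shaft)) {
    idx <- which(shaft == s)
    if (length(idx) < 2) {
      warning(sprintf("shaft '%s' has fewer than 2 contacts; skipped", s))
      next
    }
    for (i in seq_len(length(idx) - 1)) {
      a <- idx[i]; b <- idx[i + 1]
      chans[[length(chans) + 1]] <- raw[a, ] - raw[b, ]
      m <- data.frame(shaft = s, contact_a = a, contact_b = b)
      if (!is.null(contact_meta)) {
        for (col in intersect(c("x", "y", "z"), names(contact_meta))) {
          m[[col]] <- (contact_meta[[col]][a] + contact_meta[[col]][b]) / 2
        }
        extra <- setdiff(names(contact_meta), c("x", "y", "z"))
        for (col in extra) m[[col]] <- contact_meta[[col]][a]
      }
      metas[[length(metas) + 1]] <- m
    }
  }
  if (!length(chans)) stop("no shaft yielded a bipolar channel")
  list(data = do.call(rbind, chans), channel_meta = do.call(rbind, metas))
}

#' Epoch a continuous recording, detrend and decimate
#'
#' Cuts `[onset - pre, onset + post]` around each movie onset, removes a
#' per-trial linear trend, and resamples to `fs_out` by Fourier (spectral)
#' resampling of the fixed-length segment, which is inherently
#' anti-aliased; the per-trial detrend removes the segment discontinuity
#' that periodic resampling is sensitive to, and window-edge samples are
#' marked invalid downstream anyway. Onsets too close to the edges of the
#' recording are dropped with a message.
#'
#' @param continuous Matrix `channels x samples` (a vector is one channel).
#' @param fs_in Input sampling rate (Hz).
#' @param onsets Onset times (s from recording start).
#' @param fs_out Output rate, 400 Hz by default.
#' @param pre,post Seconds kept before/after onset (1 and 3).
#' @return An [epoch_set()] (trial metadata holds the surviving onsets).
#' @export
epoch_and_detrend <- function(continuous, fs_in, onsets, fs_out = 400,
                              pre = 1, post = 3) {
  if (is.vector(continuous)) continuous <- matrix(continuous, nrow = 1)
  n <- ncol(continuous)
  n_out <- as.integer(round((pre + post) * fs_out))
  keep <- onsets - pre >= 0 & onsets + post <= n / fs_in
  if (any(!keep)) {
    message(sprintf("dropped %d trial(s) too close to the record edge",
                    sum(!keep)))
  }
  onsets <- onsets[keep]
  if (!length(onsets)) stop("no trial fits inside the recording")
  out <- array(NA_real_, c(length(onsets), nrow(continuous), n_out))
  for (tr in seq_along(onsets)) {
    i0 <- round((onsets[tr] - pre) * fs_in) + 1
    i1 <- i0 + round((pre + post) * fs_in) - 1
    for (ch in seq_len(nrow(continuous))) {
      seg <- continuous[ch, i0:i1]
      tt <- seq_along(seg)
      seg <- stats::lm.fit(cbind(1, tt), seg)$residuals
      res <- if (fs_in == fs_out) seg else fourier_resample(seg, n_out)
      out[tr, ch, ] <- res[seq_len(n_out)]
    }
  }
  epoch_set(out, fs_out, t_start = -pre,
            trial_meta = data.frame(onset = onsets))
}

# Spectral resampling: keep the Fourier bins below the output Nyquist and
# invert on the coarser grid. Exact for band-limited periodic content.
fourier_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out >= n) stop("only downsampling is supported")
  X <- stats::fft(x)
  keep <- floor(n_out / 2)
  Y <- complex(n_out)
  Y[1:keep] <- X[1:keep]
  Y[(n_out - keep + 2):n_out] <- X[(n - keep + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Hanning-taper time-frequency decomposition
#'
#' Sliding-window Fourier power with a frequency-dependent window: for
#' frequency `f` the Hanning-tapered window spans `n_cycles / f` seconds,
#' clipped to `[win_min, win_max]` (8 cycles, 0.1-1 s by default). Power
#' is evaluated on a regular time grid; points whose window would extend
#' beyond the epoch are returned as `NA` rather than zero-padded, so the
#' baseline is never contaminated by edge effects.
#'
#' @param epochs An [epoch_set()] or an array `trials x channels x samples`.
#' @param fs Sampling rate, taken from the epoch set when available.
#' @param t_start First-sample time, likewise.
#' @param freqs Analysis frequencies (Hz), 1-200 in 1 Hz steps by default.
#' @param time_step Spacing of the output time grid (s); 0.0025 s.
#' @param n_cycles Cycles per window before clipping.
#' @param win_min,win_max Window-length clip bounds (s).
#' @param out_times Optional explicit output times (s) overriding the
#'   regular grid; restricting output to the baseline plus the analysis
#'   windows bounds memory on large cohorts.
#' @param chunk Number of trial-channel signals per FFT batch.
#' @return Object of class `tfr` with `power` (`trials x channels x freqs
#'   x times`, raw units), `freqs`, `times`, `fs`.
#' @export
tfr_hanning <- function(epochs, fs = NULL, t_start = NULL, freqs = 1:200,
                        time_step = 0.0025, n_cycles = 8,
                        win_min = 0.1, win_max = 1, out_times = NULL,
                        chunk = 256) {
  if (inherits(epochs, "epoch_set")) {
    fs <- epochs$fs; t_start <- epochs$times[1]; x <- epochs$data
  } else {
    x <- epochs
    if (is.null(fs)) stop("fs required for a bare array")
    if (is.null(t_start)) t_start <- -1
  }
  stopifnot(length(dim(x)) == 3)
  if (any(freqs > fs / 2)) stop("frequency above Nyquist")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]; n_s <- dim(x)[3]
  t_end <- t_start + (n_s - 1) / fs
  times <- if (is.null(out_times)) seq(t_start, t_end, by = time_step) else
    sort(out_times)
  # output grid indexed on the sample axis (times must align with 1/fs)
  idx <- round((times - t_start) * fs) + 1
  if (max(abs((idx - 1) / fs + t_start - times)) > 1e-9) {
    stop("output times must fall on the sampling grid (multiples of 1/fs)")
  }
  nfft <- 2^ceiling(log2(2 * n_s))
  n_t <- length(times)
  # per-frequency complex kernels, FFT'd once
  halves <- integer(length(freqs))
  KERN <- matrix(0i, nfft, length(freqs))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    wl <- min(max(n_cycles / f, win_min), win_max)
    half <- floor(wl * fs / 2)
    halves[fi] <- half
    n_win <- 2L * half + 1L
    k <- seq_len(n_win) - 1
    win <- 0.5 - 0.5 * cos(2 * pi * k / (n_win - 1))
    kern <- win * exp(-2i * pi * f * (k - half) / fs) / sum(win)
    KERN[seq_len(n_win), fi] <- kern
  }
  KERN <- stats::mvfft(KERN)
  n_sig <- n_tr * n_ch
  power <- array(NA_real_, c(n_tr, n_ch, length(freqs), n_t))
  dim(power) <- c(n_sig, length(freqs), n_t)
  flat <- matrix(aperm(x, c(3, 1, 2)), nrow = n_s)   # samples x signals
  for (c0 in seq(1, n_sig, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1, n_sig)
    sig <- matrix(0, nfft, length(cols))
    sig[seq_len(n_s), ] <- flat[, cols]
    SIG <- stats::mvfft(sig)
    for (fi in seq_along(freqs)) {
      conv <- stats::mvfft(SIG * KERN[, fi], inverse = TRUE) / nfft
      half <- halves[fi]
      # convolution lag s corresponds to a window centered at s - half
      valid <- idx >= half + 1 & idx <= n_s - half
      est <- Mod(conv[idx[valid] + half, , drop = FALSE])^2
      power[cols, fi, valid] <- t(est)
    }
  }
  dim(power) <- c(n_tr, n_ch, length(freqs), n_t)
  structure(list(power = power, freqs = freqs, times = times, fs = fs,
                 baseline = NULL, normalized = FALSE, mask = NULL),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr> %d trials x %d channels x %d freqs x %d times (%s)\n",
              d[1], d[2], d[3], d[4],
              if (x$normalized) "percent change" else "raw power"))
  if (!is.null(x$mask)) {
    cat(sprintf("  outlier mask: %.4g%% of points rejected\n",
                100 * mean(x$mask)))
  }
  invisible(x)
}

#' Baseline percent-change normalization
#'
#' Per trial, channel and frequency: `y(t) = (P(t) - P0) / P0` with `P0`
#' the mean raw power over the baseline interval. Stored as a fraction
#' (multiply by 100 to report percent). Channels/frequencies with `P0 = 0`
#' are flagged invalid (`NA`).
#'
#' @param tfr A raw-power `tfr` object.
#' @param baseline Baseline interval, `[-1, 0)` by default.
#' @return The `tfr` with `power` replaced by percent-change fractions and
#'   `baseline_power` added.
#' @export
baseline_percent_change <- function(tfr, baseline = c(-1, 0)) {
  stopifnot(inherits(tfr, "tfr"), !tfr$normalized)
  bsel <- tfr$times >= baseline[1] & tfr$times < baseline[2]
  if (!any(bsel)) stop("baseline interval outside the epoch")
  p0 <- apply(tfr$power[, , , bsel, drop = FALSE], 1:3, mean, na.rm = TRUE)
  p0[p0 == 0] <- NA_real_
  tfr$power <- sweep(sweep(tfr$power, 1:3, p0, "-"), 1:3, p0, "/")
  tfr$baseline_power <- p0
  tfr$baseline <- baseline
  tfr$normalized <- TRUE
  tfr
}

#' Reject extreme time-frequency points
#'
#' A point in trial `i` is masked when it lies more than `k` standard
#' deviations from the mean of the *other* trials at that channel,
#' frequency and time. Only points are removed, never whole trials.
#'
#' @param tfr A normalized `tfr`.
#' @param k Rejection threshold in leave-one-out SDs (10).
#' @return The `tfr` with masked points set `NA` and a logical `mask`
#'   array recorded; the rejected fraction is printed by `print.tfr`.
#' @export
reject_outlier_points <- function(tfr, k = 10) {
  stopifnot(inherits(tfr, "tfr"))
  n <- dim(tfr$power)[1]
  if (n < 3) stop("need at least 3 trials")
  if (!is.finite(k)) {   # k = Inf masks nothing
    tfr$mask <- array(FALSE, dim(tfr$power))
    return(tfr)
  }
  p <- tfr$power
  s <- apply(p, 2:4, sum, na.rm = TRUE)
  s2 <- apply(p^2, 2:4, sum, na.rm = TRUE)
  cnt <- apply(is.finite(p), 2:4, sum)
  mask <- array(FALSE, dim(p))
  for (i in seq_len(n)) {
    xi <- p[i, , , , drop = FALSE]
    dim(xi) <- dim(p)[2:4]
    fin <- is.finite(xi)
    m_oth <- (s - ifelse(fin, xi, 0)) / (cnt - fin)
    v_oth <- (s2 - ifelse(fin, xi^2, 0)) / (cnt - fin) - m_oth^2
    v_oth[v_oth < 0] <- 0
    sd_oth <- sqrt(v_oth * (cnt - fin) / (cnt - fin - 1))
    bad <- fin & abs(xi - m_oth) > k * sd_oth
    bad[!is.finite(bad)] <- FALSE
    mask[i, , , ] <- bad
  }
  tfr$power[mask] <- NA_real_
  tfr$mask <- mask
  tfr
}

#' Broadband (band-averaged) power time courses
#'
#' Mean of the percent-change power over the in-band frequencies,
#' honoring the outlier mask (masked points are excluded from the mean).
#'
#' @param tfr A normalized `tfr`.
#' @param band Frequency interval, 20-190 Hz by default (broadband power).
#' @return Array `trials x channels x times`.
#' @export
band_power <- function(tfr, band = c(20, 190)) {
  stopifnot(inherits(tfr, "tfr"))
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("band contains no analysis frequency")
  apply(tfr$power[, , sel, , drop = FALSE], c(1, 2, 4), mean, na.rm = TRUE)
}

#' Canonical frequency-band edges
#'
#' Band edges used for band-resolved coding time courses; the broadband
#' range doubles as the default of [band_power()].
#' @export
frequency_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30),
       gamma = c(30, 80), high_gamma = c(80, 190), broadband = c(20, 190))
}
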