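# Synthetic cohort generator. Emulates the statistical structure of the
# seven-patient study - rating distributions, 1/f broadband LFP with
# rating-scaled band-limited power confined to stimulus-specific windows,
# bimodal Hand motion and ramping Face action-unit profiles, and Poisson
# spike trains - so that every downstream stage of the pipeline can be
# exercised and calibrated without patient data.

#' Printed rating-probability tables
#'
#' Per-option rating probabilities (options coded 1-4) by stimulus type,
#' as printed for the patient cohort (mean over the seven patients) and
#' the control sample.
#'
#' @param cohort `"patient"` or `"control"`.
#' @return 2 x 4 matrix, rows `Hand` and `Face`, rows summing to 1.
#' @export
rating_probabilities <- function(cohort = c("patient", "control")) {
  cohort <- match.arg(cohort)
  tab <- utils::read.csv(system.file("extdata", "rating_probabilities.csv",
                                     package = "insulacoder"))
  tab <- tab[tab$cohort == cohort, ]
  m <- as.matrix(tab[, paste0("rating", 1:4)])
  dimnames(m) <- list(tab$stimulus, paste0("rating", 1:4))
  sweep(m, 1, rowSums(m), "/")   # remove rounding residue of the printed %
}

#' Specification of a synthetic cohort
#'
#' Defaults describe the emulated study: seven patients contributing 85
#' insular bipolar channels (5-19 each), 60 Hand and 60 Face trials per
#' patient covering 30 movies per type shown twice, with rating
#' probabilities from the printed patient table.
#'
#' @param n_patients Number of patients.
#' @param channels_per_patient Integer vector (length `n_patients`,
#'   entries >= 1) of channel counts.
#' @param n_trials_per_type Trials per stimulus type per patient.
#' @param rating_probs 2 x 4 probability table (rows Hand, Face; rows must
#'   sum to 1 within 1e-12).
#' @param n_movies_per_type Unique movies per stimulus type;
#'   `2 * n_trials_per_type` must be divisible by it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 7,
                        channels_per_patient = c(5, 19, 14, 12, 13, 10, 12),
                        n_trials_per_type = 60,
                        rating_probs = rating_probabilities("patient"),
                        n_movies_per_type = 30) {
  stopifnot(length(channels_per_patient) == n_patients,
            all(channels_per_patient >= 1),
            n_trials_per_type >= 1)
  rating_probs <- as.matrix(rating_probs)
  if (!all(dim(rating_probs) == c(2, 4))) {
    stop("rating_probs must be a 2 x 4 table (stimulus x rating option)")
  }
  if (any(abs(rowSums(rating_probs) - 1) > 1e-12) || any(rating_probs < 0)) {
    stop("rating_probs rows must be probabilities summing to 1")
  }
  if (n_trials_per_type %% n_movies_per_type != 0) {
    stop("n_trials_per_type must be a multiple of n_movies_per_type")
  }
  rownames(rating_probs) <- c("Hand", "Face")
  structure(list(n_patients = n_patients,
                 channels_per_patient = channels_per_patient,
                 n_trials_per_type = n_trials_per_type,
                 rating_probs = rating_probs,
                 n_movies_per_type = n_movies_per_type),
            class = "cohort_spec")
}

#' Specification of injected intensity coding
#'
#' Describes which channels carry rating-scaled broadband power and
#' where: band-limited (20-190 Hz) power is multiplied by
#' `1 + effect_gain * (rating - 1)` inside the stimulus-matched window
#' only. Hand coding lives in the early window, Face coding in the
#' two-part late window.
#'
#' @param coding_channels_hand,coding_channels_face Channel indices (into
#'   the pooled channel axis) carrying Hand / Face coding; a channel may
#'   appear in both (dual coding).
#' @param effect_gain Fractional power increase per rating step (>= 0).
#' @param hand_window Interval (s) of Hand coding.
#' @param face_window Two-column matrix of Face-coding sub-intervals.
#' @param band Modulated frequency band (Hz), within [1, 200].
#' @param noise_exponent Spectral slope of the 1/f background.
#' @return Object of class `coding_spec`.
#' @export
coding_spec <- function(coding_channels_hand = integer(0),
                        coding_channels_face = integer(0),
                        effect_gain = 0.5,
                        hand_window = c(1.01, 1.44),
                        face_window = matrix(c(1.75, 1.86, 1.91, 1.98),
                                             2, 2, byrow = TRUE),
                        band = c(20, 190),
                        noise_exponent = 1) {
  if (is.vector(face_window)) face_window <- matrix(face_window, 1, 2)
  windows <- rbind(matrix(hand_window, 1, 2), face_window)
  if (any(windows[, 1] <= 1) || any(windows[, 2] > 2) ||
      any(windows[, 1] >= windows[, 2])) {
    stop("coding windows must lie within (1, 2]")
  }
  if (band[1] < 1 || band[2] > 200 || band[1] >= band[2]) {
    stop("band must lie within [1, 200]")
  }
  if (effect_gain < 0) stop("effect_gain must be >= 0")
  structure(list(coding_channels_hand = as.integer(coding_channels_hand),
                 coding_channels_face = as.integer(coding_channels_face),
                 effect_gain = effect_gain,
                 hand_window = matrix(hand_window, 1, 2),
                 face_window = face_window,
                 band = band, noise_exponent = noise_exponent),
            class = "coding_spec")
}

#' Generate a synthetic rating table
#'
#' One row per trial per patient. The trial sequence (stimulus type and
#' movie id) is drawn once and shared by all patients, mimicking a fixed
#' randomized presentation order; each movie appears
#' `2 * n_trials_per_type / n_movies_per_type` times per type. Ratings
#' are sampled independently per trial from the stimulus-specific
#' probability row.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of class `rating_table`: `patient`, `trial`,
#'   `stimulus`, `movie`, `rating`; the cohort spec is attached as attribute
#'   `cohort_spec`.
#' @export
generate_ratings <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  reps <- spec$n_trials_per_type / spec$n_movies_per_type
  seq_stim <- rep(c("Hand", "Face"), each = spec$n_trials_per_type)
  seq_movie <- rep(rep(seq_len(spec$n_movies_per_type), reps), 2)
  ord <- sample(length(seq_stim))
  seq_stim <- seq_stim[ord]; seq_movie <- seq_movie[ord]
  n_tr <- length(seq_stim)
  out <- do.call(rbind, lapply(seq_len(spec$n_patients), function(p) {
    rating <- integer(n_tr)
    for (s in c("Hand", "Face")) {
      i <- seq_stim == s
      rating[i] <- sample.int(4, sum(i), replace = TRUE,
                              prob = spec$rating_probs[s, ])
    }
    data.frame(patient = p, trial = seq_len(n_tr), stimulus = seq_stim,
               movie = seq_movie, rating = rating)
  }))
  class(out) <- c("rating_table", "data.frame")
  attr(out, "cohort_spec") <- spec
  out
}

#' Mean rating per movie
#'
#' Empirical mean rating of each (stimulus, movie) across all trials and
#' patients; the movie-level intensity used by the feature generator and
#' by the decoding analyses.
#'
#' @param ratings A `rating_table`.
#' @return Data frame: `stimulus`, `movie`, `mean_rating`, `n_trials`.
#' @export
movie_mean_ratings <- function(ratings) {
  agg <- stats::aggregate(rating ~ stimulus + movie, data = ratings, mean)
  cnt <- stats::aggregate(rating ~ stimulus + movie, data = ratings, length)
  data.frame(stimulus = agg$stimulus, movie = agg$movie,
             mean_rating = agg$rating, n_trials = cnt$rating)
}

# Gaussian noise with a prescribed amplitude per rFFT bin.
# ampl: length floor(n/2) + 1 (DC first). Returns one realization per
# column of a `batch`-column matrix.
spectral_noise <- function(n, ampl, batch = 1) {
  half <- floor(n / 2)
  stopifnot(length(ampl) == half + 1)
  X <- matrix(0i, n, batch)
  nz <- 2:half   # skip DC; handle Nyquist separately for even n
  re <- matrix(stats::rnorm((half - 1) * batch), half - 1, batch)
  im <- matrix(stats::rnorm((half - 1) * batch), half - 1, batch)
  X[nz, ] <- (re + 1i * im) / sqrt(2) * ampl[nz]
  if (n %% 2 == 0) {
    X[half + 1, ] <- stats::rnorm(batch) * ampl[half + 1]
  }
  X[n - nz + 2, ] <- Conj(X[nz, ])
  Re(stats::mvfft(X, inverse = TRUE)) / n * sqrt(n)
}

# Expected variance of spectral_noise output given bin amplitudes.
spectral_variance <- function(n, ampl) {
  half <- floor(n / 2)
  v <- 2 * sum(ampl[2:half]^2)
  if (n %% 2 == 0) v <- v + ampl[half + 1]^2
  v / n
}

#' Generate synthetic epoched LFP trials
#'
#' Each trial and channel is 1/f-spectrum background noise over
#' `[-1, 3]` s at `fs` Hz, plus a band-limited (default 20-190 Hz)
#' component whose baseline variance matches the background's in-band
#' variance. For coding channels, the band component's power is
#' multiplied by `1 + effect_gain * (rating - 1)` inside the
#' stimulus-matched window of stimulus-matched trials (25 ms cosine
#' ramps at the window edges); non-coding channels and non-matching
#' trials carry no rating dependence.
#'
#' @param ratings A `rating_table` from [generate_ratings()].
#' @param coding A [coding_spec()].
#' @param fs Sampling rate (400 Hz).
#' @return An [epoch_set()] whose `trial_meta` is the shared trial
#'   sequence and whose `channel_meta` maps channels to patients;
#'   the full rating table is attached as `$ratings`.
#' @export
generate_lfp_trials <- function(ratings, coding, fs = 400) {
  stopifnot(inherits(ratings, "rating_table"), inherits(coding, "coding_spec"))
  spec <- attr(ratings, "cohort_spec")
  n_ch_total <- sum(spec$channels_per_patient)
  bad <- setdiff(c(coding$coding_channels_hand, coding$coding_channels_face),
                 seq_len(n_ch_total))
  if (length(bad)) stop("coding channel index out of range: ",
                        paste(bad, collapse = ", "))
  n <- as.integer(4 * fs)
  times <- -1 + (seq_len(n) - 1) / fs
  if (max(coding$hand_window, coding$face_window) > max(times)) {
    stop("coding window outside the epoch")
  }
  freqs_bin <- (0:(n / 2)) * fs / n
  ampl_bg <- c(0, freqs_bin[-1]^(-coding$noise_exponent / 2))
  ampl_bg <- ampl_bg / sqrt(spectral_variance(n, ampl_bg))  # unit variance
  in_band <- freqs_bin >= coding$band[1] & freqs_bin <= coding$band[2]
  # background variance inside the band, for matching the injected component
  var_band_bg <- spectral_variance(n, ifelse(in_band, ampl_bg, 0))
  ampl_band <- ifelse(in_band, 1, 0)
  ampl_band <- ampl_band / sqrt(spectral_variance(n, ampl_band)) *
    sqrt(var_band_bg)
  win_env <- function(win_mat, ramp = 0.025) {
    w <- rep(0, n)
    for (i in seq_len(nrow(win_mat))) {
      a <- win_mat[i, 1]; b <- win_mat[i, 2]
      up <- times >= a - ramp & times < a
      dn <- times > b & times <= b + ramp
      w[times >= a & times <= b] <- 1
      w[up] <- 0.5 - 0.5 * cos(pi * (times[up] - a + ramp) / ramp)
      w[dn] <- 0.5 + 0.5 * cos(pi * (times[dn] - b) / ramp)
    }
    w
  }
  env_hand <- win_env(coding$hand_window)
  env_face <- win_env(coding$face_window)
  pat_of_ch <- rep(seq_len(spec$n_patients), spec$channels_per_patient)
  trial_meta <- unique(ratings[, c("trial", "stimulus", "movie")])
  trial_meta <- trial_meta[order(trial_meta$trial), ]
  rownames(trial_meta) <- NULL
  n_tr <- nrow(trial_meta)
  rating_mat <- matrix(NA_integer_, spec$n_patients, n_tr)
  for (p in seq_len(spec$n_patients)) {
    rp <- ratings[ratings$patient == p, ]
    rating_mat[p, rp$trial] <- rp$rating
  }
  data <- array(NA_real_, c(n_tr, n_ch_total, n))
  for (ch in seq_len(n_ch_total)) {
    bg <- spectral_noise(n, ampl_bg, batch = n_tr)
    bd <- spectral_noise(n, ampl_band, batch = n_tr)
    codes_hand <- ch %in% coding$coding_channels_hand
    codes_face <- ch %in% coding$coding_channels_face
    for (tr in seq_len(n_tr)) {
      r <- rating_mat[pat_of_ch[ch], tr]
      stim <- trial_meta$stimulus[tr]
      env <- rep(1, n)
      gain_fac <- sqrt(1 + coding$effect_gain * (r - 1))
      if (codes_hand && stim == "Hand") {
        env <- env + (gain_fac - 1) * env_hand
      }
      if (codes_face && stim == "Face") {
        env <- env + (gain_fac - 1) * env_face
      }
      data[tr, ch, ] <- bg[, tr] + bd[, tr] * env
    }
  }
  es <- epoch_set(data, fs, t_start = -1, trial_meta = trial_meta,
                  channel_meta = data.frame(channel = seq_len(n_ch_total),
                                            patient = pat_of_ch,
                                            insula = TRUE))
  es$ratings <- ratings
  es$coding <- coding
  es
}

#' Per-patient ratings aligned to the shared trial grid
#'
#' @param es An epoch set from [generate_lfp_trials()].
#' @param channel Channel index; the ratings of that channel's patient
#'   are returned, aligned to the trial dimension.
#' @return Integer vector of ratings.
#' @export
trial_ratings <- function(es, channel) {
  p <- es$channel_meta$patient[channel]
  rp <- es$ratings[es$ratings$patient == p, ]
  rp$rating[order(rp$trial)]
}

#' Generate synthetic stimulus features
#'
#' Frame-resolved motion and facial-shape signals per movie, built from
#' each movie's empirical mean rating (its intensity). Hand movies: a
#' rating-independent lift bump near 0.5 s and a slap bump near 1.0 s
#' whose amplitude increases with intensity. Face movies: a motion bump
#' after 1 s and logistic AU4/AU7 ramps starting around 1.1 s whose
#' plateau increases with intensity. 50 frames per 2 s movie (25 fps);
#' the motion signal pairs consecutive frames (length `n_frames - 1`).
#'
#' @param ratings A `rating_table`.
#' @param n_frames Frames per movie.
#' @return Data frame of class `stimulus_features`: `stimulus`, `movie`,
#'   `intensity`, `frame`, `time`, `motion` (`NA` on the first frame),
#'   `au4`, `au7`, `shape` (`NA` for Hand movies).
#' @export
generate_stimulus_features <- function(ratings, n_frames = 50) {
  movies <- movie_mean_ratings(ratings)
  fps <- n_frames / 2
  t_frame <- seq_len(n_frames) / fps
  bump <- function(t0, sd) exp(-(t_frame - t0)^2 / (2 * sd^2))
  ramp <- function(plateau, t0, tau) plateau / (1 + exp(-(t_frame - t0) / tau))
  out <- do.call(rbind, lapply(seq_len(nrow(movies)), function(i) {
    s <- movies$stimulus[i]; v <- movies$mean_rating[i]
    if (s == "Hand") {
      motion <- 1.0 * bump(0.5, 0.08) + (0.4 + 0.3 * v) * bump(1.0, 0.07)
      au4 <- au7 <- shape <- rep(NA_real_, n_frames)
    } else {
      motion <- (0.45 + 0.1 * v) * bump(1.2, 0.15)
      au4 <- ramp(pmin(0.10 + 0.18 * v, 1), 1.15, 0.08)
      au7 <- ramp(pmin(0.08 + 0.15 * v, 1), 1.10, 0.08)
      shape <- (au4 + au7) / 2
    }
    motion[1] <- NA_real_   # defined per consecutive frame pair
    data.frame(stimulus = s, movie = movies$movie[i], intensity = v,
               frame = seq_len(n_frames), time = t_frame,
               motion = motion, au4 = au4, au7 = au7, shape = shape)
  }))
  class(out) <- c("stimulus_features", "data.frame")
  out
}

#' Movies x frames matrix of one feature signal
#'
#' @param features A `stimulus_features` frame.
#' @param signal `"motion"` or `"shape"`.
#' @param stimulus `"Hand"` or `"Face"`.
#' @return List: `X` (movies x frames, first all-`NA` motion frame
#'   dropped), `intensity` (per movie), `movie`, `time`.
#' @export
feature_matrix <- function(features, signal = c("motion", "shape"),
                           stimulus = c("Hand", "Face")) {
  signal <- match.arg(signal); stimulus <- match.arg(stimulus)
  f <- features[features$stimulus == stimulus, ]
  movies <- sort(unique(f$movie))
  tt <- sort(unique(f$time))
  X <- t(vapply(movies, function(m) f[[signal]][f$movie == m][order(f$time[f$movie == m])],
                numeric(length(tt))))
  keep <- colSums(is.finite(X)) > 0
  list(X = X[, keep, drop = FALSE],
       intensity = vapply(movies, function(m) f$intensity[f$movie == m][1],
                          numeric(1)),
       movie = movies, time = tt[keep])
}

#' Generate synthetic spike trains
#'
#' Inhomogeneous Poisson spike trains per unit and trial: rate
#' `base_rate` during baseline and neutral periods, and `base_rate *
#' (1 + gain * (rating - 1))` during the pain period (1-2 s).
#'
#' @param ratings A `rating_table`.
#' @param base_rate Baseline rate (Hz, >= 1).
#' @param gain Fractional rate increase per rating step.
#' @param n_units Units to simulate.
#' @param patient Whose ratings drive the pain-period rate.
#' @param stimulus Optional stimulus-type subset.
#' @return List of units; each unit is a list of per-trial sorted spike
#'   time vectors over `[-1, 3]` s, with the matching ratings attached
#'   as attribute `ratings`.
#' @export
generate_spike_trains <- function(ratings, base_rate = 5, gain = 1,
                                  n_units = 1, patient = 1,
                                  stimulus = NULL) {
  if (base_rate < 1) stop("base_rate must be at least 1 Hz")
  rp <- ratings[ratings$patient == patient, ]
  if (!is.null(stimulus)) rp <- rp[rp$stimulus == stimulus, ]
  rp <- rp[order(rp$trial), ]
  pain_rates <- base_rate * (1 + gain * (rp$rating - 1))
  if (any(pain_rates < 0)) stop("negative pain-period rate")
  units <- lapply(seq_len(n_units), function(u) {
    trains <- lapply(seq_len(nrow(rp)), function(i) {
      seg <- function(t0, t1, rate) {
        k <- stats::rpois(1, rate * (t1 - t0))
        if (k == 0) return(numeric(0))
        sort(stats::runif(k, t0, t1))
      }
      c(seg(-1, 1, base_rate), seg(1, 2, pain_rates[i]),
        seg(2, 3, base_rate))
    })
    attr(trains, "ratings") <- rp$rating
    attr(trains, "stimulus") <- rp$stimulus
    trains
  })
  units
}
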