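test_that("cohort spec validates its probability table and channel counts", {
  expect_error(cohort_spec(rating_probs = matrix(c(0.5, 0.4, 0.05, 0.02,
                                                   0.25, 0.25, 0.25, 0.25),
                                                 2, 4, byrow = TRUE)),
               "summing to 1")
  expect_error(cohort_spec(channels_per_patient = rep(0, 7)), ">= 1")
  expect_error(cohort_spec(n_trials_per_type = 50), "multiple")
  sp <- cohort_spec()
  expect_equal(sum(sp$channels_per_patient), 85)
  expect_equal(sp$n_patients, 7)
})

test_that("generated ratings follow the requested distributions", {
  set.seed(601)
  # degenerate distribution: all ratings are option 1
  probs <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  sp <- cohort_spec(n_patients = 1, channels_per_patient = 1,
                    rating_probs = probs)
  expect_true(all(generate_ratings(sp)$rating == 1))
  # control-mean Hand probabilities at n = 6000: within 3 SE
  spc <- cohort_spec(n_patients = 100, channels_per_patient = rep(1, 100),
                     rating_probs = rating_probabilities("control"))
  rt <- generate_ratings(spc)
  hand <- rt[rt$stimulus == "Hand", ]
  expect_equal(nrow(hand), 6000)
  p_hat <- tabulate(hand$rating, 4) / 6000
  p0 <- rating_probabilities("control")["Hand", ]
  se <- sqrt(p0 * (1 - p0) / 6000)
  expect_true(all(abs(p_hat - p0) < 3 * se))
  # uniform probabilities at n = 1e5: chi-square goodness of fit holds
  spu <- cohort_spec(n_patients = 1, channels_per_patient = 1,
                     n_trials_per_type = 50000, n_movies_per_type = 25,
                     rating_probs = matrix(0.25, 2, 4))
  rtu <- generate_ratings(spu)
  gof <- chisq.test(tabulate(rtu$rating, 4))
  expect_gt(gof$p.value, 0.001)
  # balanced stimulus types and shared trial sequence across patients
  rt2 <- generate_ratings(cohort_spec(n_patients = 3,
                                      channels_per_patient = c(2, 2, 2)))
  expect_equal(as.vector(table(rt2$stimulus[rt2$patient == 1])), c(60, 60))
  seqs <- split(paste(rt2$stimulus, rt2$movie), rt2$patient)
  expect_equal(seqs[[1]], seqs[[2]])
})

test_that("fixed seeds reproduce the generator byte for byte", {
  gen <- function() {
    set.seed(77)
    sp <- small_cohort(n_patients = 1, channels = 2, trials_per_type = 10,
                       movies = 10)
    rt <- generate_ratings(sp)
    es <- generate_lfp_trials(rt, coding_spec(coding_channels_hand = 1))
    ft <- generate_stimulus_features(rt)
    st <- generate_spike_trains(rt, n_units = 2)
    list(rt, es$data, ft, st)
  }
  expect_identical(gen(), gen())
})

test_that("background noise has the requested spectral slope", {
  set.seed(602)
  n <- 1600; fs <- 400
  fbin <- (0:(n / 2)) * fs / n
  ampl <- c(0, fbin[-1]^(-0.5))   # 1/f power target
  x <- insulacoder:::spectral_noise(n, ampl, batch = 200)
  pw <- abs(mvfft(x))^2
  sel <- fbin > 5 & fbin < 150
  m <- rowMeans(pw[which(sel), ])
  fit <- lm(log(m) ~ log(fbin[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.2)
})

test_that("injected coding is confined to matching channels, windows and trials", {
  set.seed(603)
  sp <- small_cohort(n_patients = 1, channels = 4, trials_per_type = 60)
  rt <- generate_ratings(sp)
  cs <- coding_spec(coding_channels_hand = 1, coding_channels_face = 2,
                    effect_gain = 1.5)
  es <- generate_lfp_trials(rt, cs)
  qb <- quick_bbp(es)
  hand <- es$trial_meta$stimulus == "Hand"
  early <- period_average(qb$bbp, qb$times, "early")
  late <- period_average(qb$bbp, qb$times, "late")
  r_of <- function(avg, trials, ch) {
    cor(avg[trials, ch], trial_ratings(es, ch)[trials], method = "spearman")
  }
  # hand-coding channel codes hand trials in the early window ...
  expect_gt(r_of(early, hand, 1), 0.4)
  # ... but not face trials, and not the face-only channel
  expect_lt(abs(r_of(early, !hand, 1)), 0.3)
  expect_lt(abs(r_of(early, hand, 2)), 0.3)
  # face-coding channel codes face trials in the late window
  expect_gt(r_of(late, !hand, 2), 0.4)
  # non-coding channels carry no rating dependence anywhere
  expect_lt(abs(r_of(early, hand, 3)), 0.3)
  expect_lt(abs(r_of(late, !hand, 4)), 0.3)
})

test_that("zero gain leaves per-channel coding centered on zero", {
  set.seed(604)
  sp <- small_cohort(n_patients = 1, channels = 30, trials_per_type = 30)
  rt <- generate_ratings(sp)
  es <- generate_lfp_trials(rt, coding_spec(effect_gain = 0,
                                            coding_channels_hand = 1:30))
  qb <- quick_bbp(es)
  hand <- es$trial_meta$stimulus == "Hand"
  avg <- period_average(qb$bbp, qb$times, "early")
  rs <- vapply(1:30, function(ch) {
    cor(avg[hand, ch], trial_ratings(es, ch)[hand], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(30))
})

test_that("stimulus features scale with intensity by construction", {
  set.seed(605)
  rt <- generate_ratings(small_cohort(n_patients = 3, channels = 1))
  ft <- generate_stimulus_features(rt)
  face <- ft[ft$stimulus == "Face", ]
  lo <- face[face$intensity == min(face$intensity), ]
  hi <- face[face$intensity == max(face$intensity), ]
  # late-plateau shape signal increases with intensity
  expect_lt(mean(lo$shape[lo$time > 1.6]), mean(hi$shape[hi$time > 1.6]))
  # hand lift bump identical across ratings, slap bump increasing
  hand <- ft[ft$stimulus == "Hand", ]
  lift <- function(m) hand$motion[hand$movie == m & hand$time == 0.48]
  slap <- function(m) hand$motion[hand$movie == m & hand$time == 1.00]
  movs <- unique(hand$movie)
  expect_lt(diff(range(vapply(movs, lift, numeric(1)))), 1e-6)
  ints <- vapply(movs, function(m) hand$intensity[hand$movie == m][1],
                 numeric(1))
  slaps <- vapply(movs, slap, numeric(1))
  expect_gt(cor(ints, slaps), 0.999)
  # 50 frames per 2 s movie, motion defined per frame pair
  expect_equal(sum(ft$movie == 1 & ft$stimulus == "Hand"), 50)
  expect_equal(sum(is.finite(hand$motion[hand$movie == movs[1]])), 49)
})

test_that("spike trains have rating-scaled pain rates and rare empty windows", {
  set.seed(606)
  rt <- generate_ratings(small_cohort(n_patients = 1, channels = 1))
  st <- generate_spike_trains(rt, base_rate = 5, gain = 1, n_units = 1,
                              stimulus = "Hand")[[1]]
  ratings <- attr(st, "ratings")
  counts <- spike_counts(st, c(1, 2))
  base <- spike_counts(st, c(-1, 0))
  # pain-period mean near base * (1 + rating - 1), baseline near base
  expect_equal(mean(base), 5, tolerance = 1)
  expect_gt(mean(counts[ratings == 4]), mean(counts[ratings == 1]))
  # kendall power check at gain 1
  set.seed(607)
  hits <- replicate(60, {
    u <- generate_spike_trains(rt, base_rate = 5, gain = 1,
                               stimulus = "Hand")[[1]]
    spike_intensity_coding(spike_counts(u, c(1, 2)),
                           attr(u, "ratings"))$p1 < 0.05
  })
  expect_gt(mean(hits), 0.5)
  # empty pain windows are rare when 5 spikes are expected
  many <- generate_spike_trains(rt, base_rate = 5, gain = 0, n_units = 20)
  empt <- mean(unlist(lapply(many, function(u) spike_counts(u, c(1, 2)) == 0)))
  expect_lt(empt, 0.02)
  expect_error(generate_spike_trains(rt, base_rate = 0.5), "at least 1")
  expect_error(generate_spike_trains(rt, gain = -0.5), "negative")
})
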