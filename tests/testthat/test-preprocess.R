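test_that("bipolar re-referencing differences adjacent contacts", {
  raw <- rbind(a = c(1, 2, 3), b = c(0, 1, 1), c = c(2, 2, 2))
  out <- bipolar_rereference(raw, shaft = rep("s1", 3))
  expect_equal(nrow(out$data), 2)
  expect_equal(out$data[1, ], c(1, 1, 2))   # a - b
  expect_equal(out$data[2, ], c(-2, -1, -1))  # b - c
  # common-mode rejection
  same <- matrix(rnorm(10), 2, 5, byrow = TRUE)
  same[2, ] <- same[1, ]
  expect_equal(bipolar_rereference(same, c("s", "s"))$data[1, ], rep(0, 5))
  # midpoint coordinates
  meta <- data.frame(x = c(0, 2, 4), y = c(0, 0, 0), z = c(1, 3, 5))
  out2 <- bipolar_rereference(raw, rep("s1", 3), meta)
  expect_equal(out2$channel_meta$x, c(1, 3))
  expect_equal(out2$channel_meta$z, c(2, 4))
  expect_warning(bipolar_rereference(raw, c("s1", "s1", "lone")), "skipped")
})

test_that("study-sized shaft layout yields 85 bipolar channels from 102 contacts", {
  # 7 patients, shafts of |contacts| summing to 102 with 17 shafts:
  # 102 contacts - 17 shafts = 85 adjacent pairs
  shaft_sizes <- c(8, 5, 7, 4, 6, 8, 5, 6, 7, 5, 6, 8, 4, 7, 6, 5, 5)
  expect_equal(sum(shaft_sizes), 102)
  shaft <- rep(seq_along(shaft_sizes), shaft_sizes)
  raw <- matrix(rnorm(102 * 4), 102, 4)
  out <- bipolar_rereference(raw, shaft)
  expect_equal(nrow(out$data), 85)
})

test_that("epoching detrends, decimates and sizes trials correctly", {
  fs_in <- 1024
  t <- seq(0, 10, by = 1 / fs_in)
  # linear ramp vanishes after detrending
  ramp <- 5 * t
  es <- epoch_and_detrend(ramp, fs_in, onsets = 5)
  expect_equal(dim(es$data), c(1, 1, 1600))
  expect_lt(max(abs(es$data)), 1e-9 * max(ramp))
  # a 30 Hz sinusoid survives 1024 -> 400 Hz resampling within 1%
  sine <- sin(2 * pi * 30 * t)
  es2 <- epoch_and_detrend(sine, fs_in, onsets = 5)
  interior <- es2$data[1, 1, 200:1400]
  expect_equal(max(abs(interior)), 1, tolerance = 0.01)
  # onset too close to the edge is dropped with a message
  expect_message(es3 <- epoch_and_detrend(sine, fs_in, onsets = c(0.5, 5)),
                 "dropped")
  expect_equal(dim(es3$data)[1], 1)
})

test_that("taper windows clip to [0.1, 1] s and powers peak at the input frequency", {
  fs <- 400
  wl <- function(f) min(max(8 / f, 0.1), 1)
  expect_equal(wl(20), 0.4)
  expect_equal(wl(4), 1.0)
  expect_equal(wl(150), 0.1)
  expect_error(tfr_hanning(array(0, c(1, 1, 800)), fs = fs, freqs = 250),
               "Nyquist")
  t <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  x <- array(sin(2 * pi * 40 * t), c(1, 1, length(t)))
  tf <- tfr_hanning(x, fs = fs, freqs = seq(30, 50, 1), time_step = 0.01)
  interior <- tf$times > 0 & tf$times < 2
  peak <- tf$freqs[which.max(rowMeans(tf$power[1, 1, , interior]))]
  expect_equal(peak, 40, tolerance = 1)
  # edge samples whose window exceeds the epoch are invalid, not zero
  expect_true(all(is.na(tf$power[1, 1, 1, tf$times < -0.9])))
})

test_that("tfr is shift covariant at interior points", {
  set.seed(5)
  fs <- 400
  n <- 1600
  shift <- 40   # samples = 0.1 s
  x <- rnorm(n)
  a <- array(x, c(1, 1, n))
  b <- array(c(rep(0, shift), x[1:(n - shift)]), c(1, 1, n))
  tfa <- tfr_hanning(a, fs = fs, freqs = c(25, 60), time_step = 0.0025)
  tfb <- tfr_hanning(b, fs = fs, freqs = c(25, 60), time_step = 0.0025)
  ia <- 300:900
  expect_equal(tfb$power[1, 1, , ia + shift], tfa$power[1, 1, , ia],
               tolerance = 1e-8)
})

test_that("white-noise spectrum is flat across frequencies", {
  set.seed(6)
  x <- array(rnorm(200 * 1 * 1600), c(200, 1, 1600))
  tf <- tfr_hanning(x, fs = 400, freqs = seq(20, 180, 20), time_step = 0.05)
  interior <- tf$times > -0.5 & tf$times < 2.5
  pw <- apply(tf$power[, 1, , interior], 2, mean, na.rm = TRUE)
  fit <- lm(log(pw) ~ tf$freqs)
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)   # slope not significant
})

test_that("percent change normalization follows (P - P0) / P0", {
  tf <- structure(list(
    power = array(2, c(4, 1, 2, 20)),
    freqs = c(10, 20), times = seq(-1, 0.9, by = 0.1), fs = 10,
    normalized = FALSE, mask = NULL), class = "tfr")
  out <- baseline_percent_change(tf)
  expect_equal(unique(as.vector(out$power)), 0)       # P == P0 -> 0
  tf$power[, , , 11:20] <- 4                          # P = 2 P0 -> 1
  out2 <- baseline_percent_change(tf)
  expect_equal(unique(as.vector(out2$power[, , , 11:20])), 1)
  # stationary noise: mean percent change over the pain period ~ 0
  set.seed(7)
  tf$power <- array(rexp(500 * 1 * 2 * 20), c(500, 1, 2, 20))
  out3 <- baseline_percent_change(tf)
  m <- mean(out3$power[, , , 11:20])
  se <- sd(out3$power[, , , 11:20]) / sqrt(500 * 2 * 10)
  expect_lt(abs(m), 10 * se)  # loose: trials share baselines across times
})

test_that("outlier rejection masks single extreme points only", {
  set.seed(8)
  tf <- structure(list(
    power = array(rnorm(50 * 2 * 3 * 30), c(50, 2, 3, 30)),
    freqs = 1:3, times = seq(-1, 1.9, by = 0.1), fs = 10,
    normalized = TRUE, mask = NULL), class = "tfr")
  clean <- reject_outlier_points(tf, k = 10)
  expect_lt(mean(clean$mask), 1e-4)     # clean data: < 0.01% rejected
  # a single injected 50 SD spike is masked, and nothing else of trial 3
  tf2 <- tf
  tf2$power[3, 1, 2, 10] <- 50
  clean2 <- reject_outlier_points(tf2, k = 10)
  expect_true(clean2$mask[3, 1, 2, 10])
  expect_equal(sum(clean2$mask[3, , , ]), 1)
  # infinite k masks nothing
  expect_equal(sum(reject_outlier_points(tf2, k = Inf)$mask), 0)
})

test_that("band averaging honors band edges and the mask", {
  pw <- array(0, c(2, 1, 3, 4))
  pw[, , 1, ] <- 1; pw[, , 2, ] <- 2; pw[, , 3, ] <- 6
  tf <- structure(list(power = pw, freqs = c(40, 50, 60),
                       times = 1:4, fs = 10, normalized = TRUE,
                       mask = NULL), class = "tfr")
  # single-frequency band returns that row
  expect_equal(band_power(tf, c(40, 40))[1, 1, ], rep(1, 4))
  # full-band mean of constants
  expect_equal(band_power(tf, c(40, 60))[1, 1, ], rep(3, 4))
  # masked frequency excluded from the mean
  tf$power[1, 1, 2, 1] <- NA
  expect_equal(band_power(tf, c(40, 60))[1, 1, 1], (1 + 6) / 2)
  expect_error(band_power(tf, c(300, 400)), "no analysis frequency")
})

test_that("normalize-then-average commutes with averaging order when baselines match", {
  set.seed(9)
  pw <- array(rexp(6 * 1 * 4 * 12), c(6, 1, 4, 12))
  pw[, , , 1:4] <- 1   # shared flat baseline P0 = 1 for every frequency
  tf <- structure(list(power = pw, freqs = c(20, 30, 40, 50),
                       times = seq(-1, 1.75, by = 0.25), fs = 4,
                       normalized = FALSE, mask = NULL), class = "tfr")
  norm_then_avg <- band_power(baseline_percent_change(tf), c(20, 50))
  tf_avg <- tf
  tf_avg$power <- array(apply(pw, c(1, 2, 4), mean), c(6, 1, 1, 12))
  tf_avg$freqs <- 35
  avg_then_norm <- band_power(baseline_percent_change(tf_avg), c(35, 35))
  expect_equal(norm_then_avg, avg_then_norm, tolerance = 1e-12)
})
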