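# Trial-wise intensity-coding statistics: rank correlations between power
# and rating, per channel, per time point, per period, and their partial /
# binned variants against stimulus features.

#' Named analysis periods (seconds post movie onset)
#'
#' The pain period is the second half of the 2 s movie; the early period is
#' the window of Hand-specific intensity coding and the late period the
#' (two-part) window of Face-specific intensity coding.
#' @return Named list of two-column matrices, one row per sub-interval.
#' @export
coding_periods <- function() {
  list(
    pain  = matrix(c(1, 2), 1, 2),
    early = matrix(c(1.01, 1.44), 1, 2),
    late  = matrix(c(1.75, 1.86, 1.91, 1.98), 2, 2, byrow = TRUE)
  )
}

#' Reference thresholds for intensity coding at n = 60 trials
#'
#' `r_sig` is the one-tailed 5% significance bound for a Spearman
#' correlation at 60 trials (see [critical_r()]); `r_absent` is the bound
#' below which a directional Bayes factor signals evidence for the absence
#' of a positive association (BF_+0 < 1/3).
#' @export
coding_thresholds <- function() c(r_sig = 0.214, r_absent = 0.085)

spearman_r <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' One-tailed p-value for a Spearman correlation (t approximation)
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom; the upper tail is the evidence for a positive
#' association. No Fisher transform is applied.
#' @param r Spearman correlation.
#' @param n Number of paired observations.
#' @keywords internal
spearman_p1 <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Spearman intensity coding of a single channel
#'
#' Rank correlation (average ranks for ties) between a per-trial neural
#' power estimate and the ordinal intensity rating, with a one-tailed
#' p-value from the t approximation.
#'
#' @param power Numeric vector, one power value per trial (e.g. broadband
#'   power averaged over a period). `NA` trials are dropped pairwise.
#' @param ratings Integer ratings 1-4, same length.
#' @return A one-row data frame with columns `r`, `p1`, `n` and a logical
#'   `defined` flag (`FALSE` when ratings or power are constant).
#' @export
spearman_coding <- function(power, ratings) {
  stopifnot(length(power) == length(ratings))
  ok <- is.finite(power) & is.finite(ratings)
  power <- power[ok]; ratings <- ratings[ok]
  n <- length(power)
  if (n < 5) stop("need at least 5 usable trials")
  if (!all(ratings %in% 1:4)) stop("ratings must be coded 1-4")
  if (length(unique(ratings)) < 2 || length(unique(power)) < 2) {
    return(data.frame(r = NA_real_, p1 = NA_real_, n = n, defined = FALSE))
  }
  r <- spearman_r(power, ratings)
  data.frame(r = r, p1 = spearman_p1(r, n), n = n, defined = TRUE)
}

#' Critical one-tailed Spearman correlation
#'
#' Smallest correlation whose one-tailed p-value (t approximation,
#' `df = n - 2`) is at most `alpha`, rounded to three decimals. At n = 60
#' and alpha = 0.05 this is the 0.214 significance bound used throughout
#' the quadrant classification.
#'
#' @param n Number of trials (>= 4).
#' @param alpha One-tailed level in (0, 1).
#' @param digits Rounding applied to the returned bound.
#' @export
critical_r <- function(n, alpha = 0.05, digits = 3) {
  if (n < 4) stop("n must be at least 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tc <- stats::qt(1 - alpha, df = n - 2)
  round(tc / sqrt(n - 2 + tc^2), digits)
}

# Spearman correlation of each column of `m` with `y`, vectorized via ranks.
col_spearman <- function(m, y) {
  ry <- rank(y)
  rm <- apply(m, 2, rank)
  suppressWarnings(as.vector(stats::cor(rm, ry)))
}

#' Time course of intensity coding
#'
#' Applies [spearman_coding()] at every time step of a broadband-power
#' array, per channel, returning the per-channel correlation time courses
#' and their channel average. Significance of temporal windows is assessed
#' separately with [circular_shift_cluster_test()].
#'
#' @param bbp Array `trials x channels x times` of (percent-change)
#'   broadband power. A matrix is treated as a single channel.
#' @param ratings Per-trial ratings 1-4.
#' @return List with `r` (`channels x times`), `mean_r` (length times), `n`.
#' @export
coding_timecourse <- function(bbp, ratings) {
  if (length(dim(bbp)) == 2) dim(bbp) <- c(dim(bbp)[1], 1, dim(bbp)[2])
  stopifnot(length(dim(bbp)) == 3, dim(bbp)[1] == length(ratings))
  n_ch <- dim(bbp)[2]; n_t <- dim(bbp)[3]
  r <- matrix(NA_real_, n_ch, n_t)
  for (ch in seq_len(n_ch)) {
    r[ch, ] <- col_spearman(bbp[, ch, , drop = TRUE], ratings)
  }
  list(r = r, mean_r = colMeans(r, na.rm = TRUE), n = length(ratings))
}

#' Partial Spearman correlation via rank residuals
#'
#' Ranks all three variables, removes the covariate by ordinary least
#' squares from the ranks of `x` and `y`, and returns the Pearson
#' correlation of the residuals.
#'
#' @param x,y Variables to correlate.
#' @param z Covariate to partial out.
#' @return Partial rank correlation, or `NA` when the covariate is
#'   constant (partials undefined).
#' @export
partial_spearman <- function(x, y, z) {
  if (length(unique(z)) < 2) return(NA_real_)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  suppressWarnings(stats::cor(ex, ey))
}

#' Binned (partial) correlations of power with motion and rating
#'
#' For each of `n_bins` consecutive time bins spanning the movie, computes
#' per channel the Spearman correlations of broadband power with the
#' stimulus motion signal and with the rating, and both partial variants
#' (each controlling for the other). Per bin, the channel-wise coefficients
#' are tested against zero with a two-tailed one-sample t-test and
#' Benjamini-Hochberg corrected across bins.
#'
#' @param bbp Array `trials x channels x bins` of power averaged per bin
#'   (six 333 ms bins over the 2 s movie in the reference analysis).
#' @param motion Matrix `trials x bins` of motion energy averaged per bin
#'   (per-movie values replicated over that movie's trials).
#' @param ratings Per-trial ratings 1-4.
#' @param q FDR level for the across-bin correction.
#' @return List with `channel` (array `channels x bins x 4` of
#'   coefficients) and `group` (data frame per bin and measure with mean r,
#'   t, p2, p_fdr, significant).
#' @export
binned_partial_correlation <- function(bbp, motion, ratings, q = 0.05) {
  stopifnot(length(dim(bbp)) == 3,
            dim(bbp)[1] == length(ratings),
            all(dim(motion) == dim(bbp)[c(1, 3)]))
  n_ch <- dim(bbp)[2]; n_bin <- dim(bbp)[3]
  measures <- c("bbp_motion", "bbp_rating", "bbp_motion_given_rating",
                "bbp_rating_given_motion")
  coefs <- array(NA_real_, c(n_ch, n_bin, 4),
                 dimnames = list(NULL, NULL, measures))
  for (b in seq_len(n_bin)) {
    m <- motion[, b]
    for (ch in seq_len(n_ch)) {
      p <- bbp[, ch, b]
      coefs[ch, b, 1] <- spearman_r(p, m)
      coefs[ch, b, 2] <- spearman_r(p, ratings)
      coefs[ch, b, 3] <- partial_spearman(p, m, ratings)
      coefs[ch, b, 4] <- partial_spearman(p, ratings, m)
    }
  }
  group <- do.call(rbind, lapply(measures, function(ms) {
    vals <- coefs[, , ms, drop = FALSE]
    tt <- lapply(seq_len(n_bin), function(b) {
      v <- vals[, b, 1]
      v <- v[is.finite(v)]
      if (length(v) < 3 || stats::sd(v) == 0) {
        return(data.frame(mean_r = mean(v), t = NA_real_, p2 = NA_real_))
      }
      ht <- stats::t.test(v)
      data.frame(mean_r = mean(v), t = unname(ht$statistic), p2 = ht$p.value)
    })
    out <- do.call(rbind, tt)
    out$bin <- seq_len(n_bin)
    out$measure <- ms
    out$p_fdr <- stats::p.adjust(out$p2, method = "BH")
    out$significant <- !is.na(out$p_fdr) & out$p_fdr < q
    out
  }))
  rownames(group) <- NULL
  list(channel = coefs, group = group)
}

#' Period-averaged intensity coding per channel
#'
#' Averages broadband power over a named period (honoring the outlier
#' mask: `NA` points are ignored, and a trial missing more than half of
#' the in-period points is excluded from that channel's correlation) and
#' correlates it with the ratings per channel.
#'
#' @param bbp Array `trials x channels x times`.
#' @param times Time axis of `bbp` (s).
#' @param ratings Per-trial ratings.
#' @param period Two-column matrix of sub-intervals, or a name from
#'   [coding_periods()].
#' @param max_missing Maximum tolerated fraction of missing in-period
#'   points per trial.
#' @return Data frame, one row per channel: `channel`, `r`, `p1`, `n`.
#' @export
period_coding <- function(bbp, times, ratings, period = "pain",
                          max_missing = 0.5) {
  avg <- period_average(bbp, times, period, max_missing)
  out <- lapply(seq_len(ncol(avg)), function(ch) {
    res <- spearman_coding(avg[, ch], ratings)
    res$channel <- ch
    res
  })
  do.call(rbind, out)[, c("channel", "r", "p1", "n", "defined")]
}

#' Per-trial power averaged over a named period
#'
#' @inheritParams period_coding
#' @return Matrix `trials x channels`; trials missing more than
#'   `max_missing` of the in-period points are `NA`.
#' @export
period_average <- function(bbp, times, period = "pain", max_missing = 0.5) {
  if (is.character(period)) period <- coding_periods()[[period]]
  if (is.vector(period)) period <- matrix(period, 1, 2)
  stopifnot(is.matrix(period), ncol(period) == 2, length(dim(bbp)) == 3)
  sel <- rep(FALSE, length(times))
  for (i in seq_len(nrow(period))) {
    sel <- sel | (times >= period[i, 1] & times <= period[i, 2])
  }
  if (!any(sel)) stop("period does not overlap the time axis")
  n_tr <- dim(bbp)[1]; n_ch <- dim(bbp)[2]
  out <- matrix(NA_real_, n_tr, n_ch)
  for (ch in seq_len(n_ch)) {
    x <- bbp[, ch, sel, drop = FALSE]
    dim(x) <- c(n_tr, sum(sel))
    miss <- rowMeans(!is.finite(x))
    avg <- rowMeans(x, na.rm = TRUE)
    avg[miss > max_missing] <- NA_real_
    out[, ch] <- avg
  }
  out
}
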