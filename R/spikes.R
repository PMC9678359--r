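# Single-unit screening and intensity coding: quality filters, stimulus
# responsiveness, rating correlation, and the spike/BBP association.

#' Unit quality filter
#'
#' Rejects sorted units with more than `max_isi_violation` of interspike
#' intervals below 2 ms or a mean firing rate below `min_rate`.
#'
#' @param isi_violation_fraction Fraction of ISIs < 2 ms.
#' @param mean_rate Mean firing rate (Hz).
#' @param max_isi_violation,min_rate Criteria (0.02 and 1 Hz).
#' @return Logical: keep the unit?
#' @export
unit_quality_filter <- function(isi_violation_fraction, mean_rate,
                                max_isi_violation = 0.02, min_rate = 1) {
  isi_violation_fraction <= max_isi_violation & mean_rate >= min_rate
}

#' Spike counts in a time window
#'
#' @param trains List with one element per trial: numeric spike times (s
#'   relative to movie onset).
#' @param window Two-element interval `[t0, t1)`.
#' @return Integer vector, one count per trial.
#' @export
spike_counts <- function(trains, window) {
  vapply(trains, function(st) sum(st >= window[1] & st < window[2]),
         numeric(1))
}

#' Stimulus responsiveness of units
#'
#' One-tailed Wilcoxon signed-rank test of per-trial spike counts in the
#' pain period (1-2 s) against the baseline (-1-0 s), irrespective of
#' rated intensity. A unit is responsive at `p1 < 0.05`. Units whose
#' counts are identical in both windows on every trial are flagged
#' (p1 = 1).
#'
#' @param units List of units; each unit is a list of per-trial spike-time
#'   vectors.
#' @param baseline,pain Counting windows.
#' @param alpha Responsiveness level.
#' @return Data frame: `unit`, `p1`, `responsive`, `flagged`.
#' @export
responsive_units <- function(units, baseline = c(-1, 0), pain = c(1, 2),
                             alpha = 0.05) {
  out <- lapply(seq_along(units), function(u) {
    trains <- units[[u]]
    if (length(trains) < 10) stop("need at least 10 trials per unit")
    cb <- spike_counts(trains, baseline)
    cp <- spike_counts(trains, pain)
    d <- cp - cb
    if (all(d == 0)) {
      return(data.frame(unit = u, p1 = 1, responsive = FALSE,
                        flagged = TRUE))
    }
    p1 <- suppressWarnings(
      stats::wilcox.test(cp, cb, paired = TRUE, alternative = "greater",
                         exact = FALSE)$p.value)
    data.frame(unit = u, p1 = p1, responsive = p1 < alpha, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Intensity coding of a unit's spike counts
#'
#' Kendall tau-b (tie-corrected, as both counts and ratings are heavily
#' tied) between pain-period spike counts and ratings for one stimulus
#' type, with a one-tailed p (normal approximation, tie-adjusted
#' variance) and a directional Bayes factor. The Bayes factor applies the
#' parametric correlation kernel of [correlation_bf_plus()] to tau and is
#' therefore an approximation (`bf_approx = TRUE` in the result).
#'
#' @param counts Per-trial spike counts (pain period).
#' @param ratings Per-trial ratings 1-4 (same stimulus type).
#' @return One-row data frame: `tau`, `p1`, `bf_plus`, `n`, `defined`,
#'   `bf_approx`.
#' @export
spike_intensity_coding <- function(counts, ratings) {
  stopifnot(length(counts) == length(ratings))
  n <- length(counts)
  if (length(unique(counts)) < 2 || length(unique(ratings)) < 2) {
    return(data.frame(tau = NA_real_, p1 = NA_real_, bf_plus = NA_real_,
                      n = n, defined = FALSE, bf_approx = TRUE))
  }
  ht <- suppressWarnings(
    stats::cor.test(counts, ratings, method = "kendall",
                    alternative = "greater", exact = FALSE))
  tau <- unname(ht$estimate)
  data.frame(tau = tau, p1 = ht$p.value,
             bf_plus = correlation_bf_plus(clamp_r(tau), n), n = n,
             defined = TRUE, bf_approx = TRUE)
}

#' Association of spike and broadband-power intensity coding across wires
#'
#' Kendall tau-b between the per-wire spike-based and BBP-based coding
#' coefficients, with one-tailed p and an (approximate) directional Bayes
#' factor.
#'
#' @param tau_spikes,tau_bbp Named or plain numeric vectors, one value
#'   per microwire, same wires in the same order.
#' @return One-row data frame: `tau`, `p1`, `bf_plus`, `n_wires`.
#' @export
spike_bbp_association <- function(tau_spikes, tau_bbp) {
  if (length(tau_spikes) != length(tau_bbp)) stop("mismatched wire sets")
  if (!is.null(names(tau_spikes)) && !is.null(names(tau_bbp)) &&
      !identical(names(tau_spikes), names(tau_bbp))) {
    stop("mismatched wire sets")
  }
  if (length(tau_spikes) < 5) stop("need at least 5 wires")
  ht <- suppressWarnings(
    stats::cor.test(tau_spikes, tau_bbp, method = "kendall",
                    alternative = "greater", exact = FALSE))
  tau <- unname(ht$estimate)
  data.frame(tau = tau, p1 = ht$p.value,
             bf_plus = correlation_bf_plus(clamp_r(tau),
                                           length(tau_spikes)),
             n_wires = length(tau_spikes))
}

# the parametric BF kernel needs |r| < 1; perfect rank agreement is mapped
# just inside the open interval
clamp_r <- function(r, eps = 1e-4) max(min(r, 1 - eps), -1 + eps)
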