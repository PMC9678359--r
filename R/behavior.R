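# Rating-behavior analytics: similarity of a participant's ratings to a
# normative (control-group) average, inclusion bounds, and the paired
# Hand-vs-Face condition contrast.

#' Similarity of a participant's ratings to a normative average
#'
#' Three metrics comparing a participant's per-movie ratings with a
#' normative mean rating: Spearman rank correlation, and slope and
#' intercept of the ordinary regression of the participant on the
#' normative ratings.
#'
#' @param participant_ratings Per-movie ratings of one participant.
#' @param normative_mean_ratings Normative mean rating per movie (same
#'   movies, same order; at least 10).
#' @return One-row data frame: `spearman_r`, `slope`, `intercept`,
#'   `defined` (`FALSE` when the normative vector is constant).
#' @export
normative_similarity <- function(participant_ratings,
                                 normative_mean_ratings) {
  stopifnot(length(participant_ratings) == length(normative_mean_ratings))
  if (length(participant_ratings) < 10) stop("need at least 10 shared movies")
  if (stats::sd(normative_mean_ratings) == 0) {
    return(data.frame(spearman_r = NA_real_, slope = NA_real_,
                      intercept = NA_real_, defined = FALSE))
  }
  fit <- stats::lm(participant_ratings ~ normative_mean_ratings)
  data.frame(
    spearman_r = suppressWarnings(
      stats::cor(participant_ratings, normative_mean_ratings,
                 method = "spearman")),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    defined = TRUE)
}

#' Leave-one-out normative similarity of the control group
#'
#' For every control, computes [normative_similarity()] against the
#' average of the *other* controls, defining the reference distribution
#' for the inclusion bounds.
#'
#' @param control_ratings Matrix `controls x movies`.
#' @return Data frame, one row per control.
#' @export
loo_normative_metrics <- function(control_ratings) {
  stopifnot(is.matrix(control_ratings), nrow(control_ratings) >= 3)
  out <- lapply(seq_len(nrow(control_ratings)), function(i) {
    norm <- colMeans(control_ratings[-i, , drop = FALSE])
    m <- normative_similarity(control_ratings[i, ], norm)
    m$control <- i
    m
  })
  do.call(rbind, out)
}

#' Inclusion bounds from control leave-one-out metrics
#'
#' Empirical 2.5 and 97.5 percentiles of each similarity metric over the
#' control group; a participant is atypical when any metric falls outside
#' its bounds.
#'
#' @param control_loo_metrics Data frame from [loo_normative_metrics()].
#' @param participant_metrics Optional data frame of participants to flag
#'   (rows as from [normative_similarity()]).
#' @param probs Percentile bounds.
#' @return List: `bounds` (metric x c(lower, upper)), and when
#'   participants were given, `atypical` (logical matrix) per metric.
#' @export
inclusion_bounds <- function(control_loo_metrics,
                             participant_metrics = NULL,
                             probs = c(0.025, 0.975)) {
  metrics <- c("spearman_r", "slope", "intercept")
  if (nrow(control_loo_metrics) < 20) {
    warning("fewer than 20 controls: unstable percentile bounds")
  }
  bounds <- t(vapply(metrics, function(m) {
    stats::quantile(control_loo_metrics[[m]], probs, na.rm = TRUE)
  }, numeric(2)))
  colnames(bounds) <- c("lower", "upper")
  out <- list(bounds = bounds)
  if (!is.null(participant_metrics)) {
    out$atypical <- vapply(metrics, function(m) {
      v <- participant_metrics[[m]]
      v < bounds[m, "lower"] | v > bounds[m, "upper"]
    }, logical(nrow(participant_metrics)))
    if (is.vector(out$atypical)) {
      out$atypical <- matrix(out$atypical, nrow = nrow(participant_metrics),
                             dimnames = list(NULL, metrics))
    }
  }
  out
}

#' Paired Hand-vs-Face condition contrast
#'
#' Paired comparison of per-participant means between the two stimulus
#' types. Normality of the differences is checked with a Shapiro-Wilk
#' test; if retained, a paired t-test is used, otherwise a Wilcoxon
#' signed-rank test. A default JZS Bayes factor ([jzs_ttest_bf()], Cauchy
#' scale 0.707) on the differences accompanies either route (an
#' approximation to a nonparametric Bayes factor when the t-test route
#' was rejected).
#'
#' @param hand,face Paired per-participant values (n >= 3).
#' @param shapiro_alpha Normality level for choosing the test.
#' @return List: `method`, `statistic`, `df` (t route only), `p2`,
#'   `bf10`, `mean_diff`, `normal`.
#' @export
condition_contrast <- function(hand, face, shapiro_alpha = 0.05) {
  stopifnot(length(hand) == length(face))
  n <- length(hand)
  if (n < 3) stop("need at least 3 paired values")
  d <- hand - face
  normal <- if (stats::sd(d) == 0) TRUE else {
    stats::shapiro.test(d)$p.value > shapiro_alpha
  }
  if (all(d == 0)) {
    return(list(method = "t", statistic = 0, df = n - 1, p2 = 1,
                bf10 = jzs_ttest_bf(0, n), mean_diff = 0, normal = TRUE))
  }
  if (normal) {
    ht <- stats::t.test(hand, face, paired = TRUE)
    t_stat <- unname(ht$statistic)
    list(method = "t", statistic = t_stat, df = n - 1, p2 = ht$p.value,
         bf10 = jzs_ttest_bf(t_stat, n), mean_diff = mean(d),
         normal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(hand, face, paired = TRUE))
    t_equiv <- mean(d) / (stats::sd(d) / sqrt(n))
    list(method = "wilcoxon", statistic = unname(ht$statistic), df = NA,
         p2 = ht$p.value, bf10 = jzs_ttest_bf(t_equiv, n),
         mean_diff = mean(d), normal = FALSE)
  }
}

#' Per-patient mean ratings of the seven-patient cohort
#'
#' Printed per-patient mean Hand and Face ratings (coded scale 1-4) and
#' their standard deviations, shipped as a plain-text table. These are
#' the inputs to the paired Hand-vs-Face contrast worked example.
#'
#' @return Data frame: `patient`, `mean_hand`, `mean_face`, `sd_hand`,
#'   `sd_face`.
#' @export
patient_rating_summary <- function() {
  utils::read.csv(system.file("extdata", "patient_rating_summary.csv",
                              package = "insulacoder"),
                  stringsAsFactors = FALSE)
}
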