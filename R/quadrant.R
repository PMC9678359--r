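# Classification of channels by Hand/Face intensity-coding profile and
# enrichment tests of dual- and single-preference coding.

#' Classify channels into stimulus-preference quadrants
#'
#' Places every channel on the (r_Hand, r_Face) plane and labels it by two
#' bounds: `r_sig`, the one-tailed significance bound for a positive
#' association (0.214 at 60 trials, see [critical_r()]), and `r_absent`,
#' the evidence-of-absence bound (BF_+0 < 1/3; reference constant 0.085
#' at 60 trials). Labels:
#' \itemize{
#'   \item `dual`: both correlations >= `r_sig`;
#'   \item `hand_pref`: Hand >= `r_sig` and Face < `r_absent`;
#'   \item `face_pref`: Face >= `r_sig` and Hand < `r_absent`;
#'   \item `inconclusive`: exactly one axis significant, the other
#'     between the bounds;
#'   \item `none`: neither axis significant.
#' }
#'
#' @param coding_hand,coding_face Data frames as from [period_coding()]
#'   (columns `channel`, `r`, `n`), computed on the same channels with
#'   equal trial counts, or bare numeric vectors of correlations.
#' @param r_sig,r_absent Bounds; defaults are the n = 60 reference
#'   constants from [coding_thresholds()]. Pass
#'   `critical_r(n)` / [correlation_bf_bound()] results for other n.
#' @return Data frame: `channel`, `r_hand`, `r_face`, `label`, plus the
#'   bounds as attributes.
#' @export
classify_channels <- function(coding_hand, coding_face,
                              r_sig = coding_thresholds()[["r_sig"]],
                              r_absent = coding_thresholds()[["r_absent"]]) {
  get_r <- function(x) if (is.data.frame(x)) x$r else as.numeric(x)
  get_ch <- function(x, m) if (is.data.frame(x)) x$channel else seq_len(m)
  r_hand <- get_r(coding_hand); r_face <- get_r(coding_face)
  if (length(r_hand) != length(r_face)) stop("mismatched channel sets")
  ch_h <- get_ch(coding_hand, length(r_hand))
  ch_f <- get_ch(coding_face, length(r_face))
  if (!identical(ch_h, ch_f)) stop("mismatched channel sets")
  if (is.data.frame(coding_hand) && is.data.frame(coding_face) &&
      !identical(coding_hand$n, coding_face$n)) {
    warning("trial counts differ between conditions; thresholds assume equal n")
  }
  label <- ifelse(
    r_hand >= r_sig & r_face >= r_sig, "dual",
    ifelse(r_hand >= r_sig & r_face < r_absent, "hand_pref",
    ifelse(r_face >= r_sig & r_hand < r_absent, "face_pref",
    ifelse(r_hand >= r_sig | r_face >= r_sig, "inconclusive", "none"))))
  out <- data.frame(channel = ch_h, r_hand = r_hand, r_face = r_face,
                    label = factor(label, levels = c("dual", "hand_pref",
                                                     "face_pref",
                                                     "inconclusive", "none")))
  attr(out, "r_sig") <- r_sig
  attr(out, "r_absent") <- r_absent
  out
}

#' Enrichment tests of quadrant occupancy
#'
#' Asks whether the dual- and single-preference quadrants hold more
#' channels than the per-site error rates alone would produce, via
#' one-sided binomial tests and their Bayes factors
#' ([binomial_test_onesided()], [binomial_bf_plus()]):
#' \itemize{
#'   \item dual among Hand-coding channels (`k` = dual, `n` = channels
#'     with `r_hand >= r_sig`, null rate `alpha`), and among Face-coding;
#'   \item Hand preference among Hand-coding channels (false "evidence of
#'     absence" rate `alpha`, re-run at `alpha_sensitivity`), and Face
#'     preference among Face-coding;
#'   \item dual as a double false positive (`k` = dual, `n` = all
#'     channels, null rate `alpha^2`).
#' }
#'
#' @param labels Output of [classify_channels()].
#' @param alpha Assumed per-site misclassification rate (0.05).
#' @param alpha_sensitivity Pessimistic rate for the sensitivity re-run
#'   of the preference tests (0.25).
#' @return List: `counts` (label histogram plus per-axis coding counts),
#'   `tests` (data frame with test, k, n, alpha0, p1, bf_plus),
#'   `hand_face_association` (Kendall tau of r_hand vs r_face across
#'   channels, reported but not thresholded).
#' @export
quadrant_enrichment <- function(labels, alpha = 0.05,
                                alpha_sensitivity = 0.25) {
  r_sig <- attr(labels, "r_sig")
  n_total <- nrow(labels)
  n_hand <- sum(labels$r_hand >= r_sig)
  n_face <- sum(labels$r_face >= r_sig)
  k_dual <- sum(labels$label == "dual")
  k_hand_pref <- sum(labels$label == "hand_pref")
  k_face_pref <- sum(labels$label == "face_pref")
  one <- function(test, k, n, a0) {
    if (n == 0) {
      return(data.frame(test = test, k = k, n = n, alpha0 = a0,
                        p1 = NA_real_, bf_plus = NA_real_))
    }
    data.frame(test = test, k = k, n = n, alpha0 = a0,
               p1 = binomial_test_onesided(k, n, a0),
               bf_plus = binomial_bf_plus(k, n, a0))
  }
  tests <- rbind(
    one("dual_among_hand_coding", k_dual, n_hand, alpha),
    one("dual_among_face_coding", k_dual, n_face, alpha),
    one("hand_pref_among_hand_coding", k_hand_pref, n_hand, alpha),
    one("hand_pref_among_hand_coding_sens", k_hand_pref, n_hand,
        alpha_sensitivity),
    one("face_pref_among_face_coding", k_face_pref, n_face, alpha),
    one("face_pref_among_face_coding_sens", k_face_pref, n_face,
        alpha_sensitivity),
    one("dual_double_false_positive", k_dual, n_total, alpha^2))
  assoc <- suppressWarnings(
    stats::cor.test(labels$r_hand, labels$r_face, method = "kendall",
                    alternative = "greater", exact = FALSE))
  list(
    counts = c(table(labels$label),
               hand_coding = n_hand, face_coding = n_face,
               total = n_total),
    tests = tests,
    hand_face_association = c(tau = unname(assoc$estimate),
                              p1 = assoc$p.value))
}
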