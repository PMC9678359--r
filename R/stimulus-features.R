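# Motion and shape information in the stimulus movies, and their temporal
# relation to the neural intensity-coding time courses.

#' Motion energy of a frame sequence
#'
#' For every pair of consecutive frames, the mean over pixels of the
#' Euclidean distance between the RGB vectors of corresponding pixels:
#' `mean(sqrt(dR^2 + dG^2 + dB^2))`.
#'
#' @param frames A list of `H x W x 3` arrays, or a 4-D array
#'   `H x W x 3 x n_frames`. All frames must share one size.
#' @return Numeric vector of length `n_frames - 1`.
#' @export
motion_energy <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 4) {
    frames <- lapply(seq_len(dim(frames)[4]), function(i) frames[, , , i])
  }
  stopifnot(is.list(frames), length(frames) >= 2)
  d1 <- dim(frames[[1]])
  out <- numeric(length(frames) - 1)
  for (i in seq_len(length(frames) - 1)) {
    a <- frames[[i]]; b <- frames[[i + 1]]
    if (!identical(dim(a), d1) || !identical(dim(b), d1)) {
      stop("frame size mismatch")
    }
    d2 <- (b - a)^2
    out[i] <- mean(sqrt(d2[, , 1] + d2[, , 2] + d2[, , 3]))
  }
  out
}

#' Pain-related shape signal from facial action units
#'
#' Elementwise mean of the brow-lowering (AU4) and eyelid-tightening
#' (AU7) activations per frame. Frames where either AU is missing are
#' linearly interpolated (constant extrapolation at the ends) and
#' flagged.
#'
#' @param au_table Data frame with columns `au4` and `au7` (activations
#'   0..1), optionally `time`; rows in frame order.
#' @return List: `shape` (per frame), `interpolated` (logical per frame).
#' @export
shape_signal <- function(au_table) {
  stopifnot(all(c("au4", "au7") %in% names(au_table)))
  shape <- (au_table$au4 + au_table$au7) / 2
  miss <- !is.finite(shape)
  if (all(miss)) stop("all frames missing")
  if (any(miss)) {
    xs <- seq_along(shape)
    shape <- stats::approx(xs[!miss], shape[!miss], xout = xs,
                           rule = 2)$y
  }
  list(shape = shape, interpolated = miss)
}

#' PLSR beta-coefficient time course of stimulus information
#'
#' Single-component PLS regression of the movie ratings on the
#' frame-resolved feature matrix: `R(i) = M(i, t) B(t) + B0`. The beta
#' time course localizes *when* the feature predicts the rating. For Face
#' movies, motion and shape are concatenated column-wise (`[M S]`) and the
#' returned betas are split per block. Cross-validated predictive
#' accuracy and its shuffle null reuse the decoding engine
#' ([cv_decode()], [shuffle_null()]).
#'
#' @param feature_matrix Matrix `movies x frames` (or `movies x 2*frames`
#'   for a `[M S]` concatenation).
#' @param ratings Mean rating per movie.
#' @param blocks Optional integer vector (length = ncol) labelling
#'   feature blocks for reporting split betas.
#' @param accuracy If `TRUE`, also compute cross-validated accuracy and a
#'   shuffle null.
#' @param n_iter,n_shuffles,inner_iter Scheme sizes forwarded to the
#'   decoding engine.
#' @return List: `beta` (per column), `beta_blocks` (split by `blocks`),
#'   `intercept`, and when requested `accuracy` (from [shuffle_null()]).
#' @export
plsr_beta_timecourse <- function(feature_matrix, ratings, blocks = NULL,
                                 accuracy = FALSE, n_iter = 100,
                                 n_shuffles = 500, inner_iter = 20) {
  feature_matrix <- as.matrix(feature_matrix)
  fit <- plsr_fit(feature_matrix, ratings, n_components = 1)
  beta <- drop(fit$coef)
  out <- list(beta = beta, intercept = fit$intercept, fit = fit)
  if (!is.null(blocks)) {
    out$beta_blocks <- split(beta, blocks)
  }
  if (accuracy) {
    out$accuracy <- shuffle_null(feature_matrix, ratings,
                                 n_shuffles = n_shuffles,
                                 inner_iter = inner_iter,
                                 n_components = 1)
  }
  out
}

#' Lagged correlation of information and coding time courses
#'
#' Correlates each channel's intensity-coding time course `r(t)` with the
#' stimulus-information beta profile `B(t + lag)` over a range of lags.
#' Positive lag means the information precedes the neural coding: at lag
#' `L`, `coding(t)` is compared with `information(t - L)`. Optionally a
#' covariate profile (shifted by the same lag) is partialled out of both
#' series (Pearson partial correlation). Per lag, the channel coefficients
#' are tested against zero (two-tailed t) and Benjamini-Hochberg corrected
#' across lags.
#'
#' @param coding_tc Matrix `channels x times` of coding coefficients (a
#'   vector is one channel).
#' @param beta_tc Information profile sampled on `info_times`.
#' @param times Time axis of `coding_tc` (s).
#' @param info_times Time axis of `beta_tc`; defaults to `times`.
#' @param lags Lags in seconds (0 to 1 s in 40 ms steps).
#' @param covariate Optional second information profile on `info_times`.
#' @param q FDR level.
#' @param min_overlap Minimum overlapping samples for a lag to be
#'   evaluated.
#' @return List: `r` (`channels x lags`), `group` data frame (lag, mean_r,
#'   t, p2, p_fdr, significant).
#' @export
lagged_information_correlation <- function(coding_tc, beta_tc, times,
                                           info_times = times,
                                           lags = seq(0, 1, by = 0.04),
                                           covariate = NULL, q = 0.05,
                                           min_overlap = 10) {
  if (is.vector(coding_tc)) coding_tc <- matrix(coding_tc, nrow = 1)
  stopifnot(ncol(coding_tc) == length(times),
            length(beta_tc) == length(info_times))
  n_ch <- nrow(coding_tc)
  r <- matrix(NA_real_, n_ch, length(lags))
  for (li in seq_along(lags)) {
    shifted_times <- info_times + lags[li]
    common <- times[times >= min(shifted_times) & times <= max(shifted_times)]
    if (length(common) < min_overlap) next
    info <- stats::approx(shifted_times, beta_tc, xout = common)$y
    cov_l <- if (!is.null(covariate)) {
      stats::approx(shifted_times, covariate, xout = common)$y
    }
    sel <- match(common, times)
    for (ch in seq_len(n_ch)) {
      x <- coding_tc[ch, sel]
      ok <- is.finite(x) & is.finite(info)
      if (!is.null(cov_l)) ok <- ok & is.finite(cov_l)
      if (sum(ok) < min_overlap) next
      if (is.null(cov_l)) {
        r[ch, li] <- suppressWarnings(stats::cor(x[ok], info[ok]))
      } else {
        ex <- stats::lm.fit(cbind(1, cov_l[ok]), x[ok])$residuals
        ey <- stats::lm.fit(cbind(1, cov_l[ok]), info[ok])$residuals
        # a covariate collinear with either series leaves no residual
        # variance: the partial correlation is undefined, not zero
        if (stats::sd(ex) < 1e-10 * max(stats::sd(x[ok]), 1e-300) ||
            stats::sd(ey) < 1e-10 * max(stats::sd(info[ok]), 1e-300)) {
          next
        }
        r[ch, li] <- suppressWarnings(stats::cor(ex, ey))
      }
    }
  }
  group <- do.call(rbind, lapply(seq_along(lags), function(li) {
    v <- r[, li]; v <- v[is.finite(v)]
    if (length(v) < 3 || stats::sd(v) == 0) {
      return(data.frame(lag = lags[li], mean_r = mean(v), t = NA_real_,
                        p2 = NA_real_))
    }
    ht <- stats::t.test(v)
    data.frame(lag = lags[li], mean_r = mean(v),
               t = unname(ht$statistic), p2 = ht$p.value)
  }))
  group$p_fdr <- stats::p.adjust(group$p2, method = "BH")
  group$significant <- !is.na(group$p_fdr) & group$p_fdr < q
  list(r = r, group = group, lags = lags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
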