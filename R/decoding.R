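# Partial least squares decoding of perceived intensity from multichannel
# broadband-power patterns (and, in the stimulus-feature module, from
# frame-resolved motion/shape profiles).

#' Partial least squares regression (PLS1, SIMPLS)
#'
#' Mean-centered PLS regression of a single response on a predictor
#' matrix, SIMPLS deflation, no unit-variance scaling. Deterministic given
#' the inputs.
#'
#' @param X Predictor matrix `observations x variables` (movies x channels
#'   or movies x frames).
#' @param y Numeric response (mean rating per movie).
#' @param n_components Number of latent components (2 for the
#'   neural-pattern decoding, 1 for the stimulus-feature analyses).
#' @return Object of class `plsr_fit`: `coef` (regression weights on the
#'   original variables), `intercept`, `x_mean`, `y_mean`, `scores`,
#'   `weights`.
#' @export
plsr_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (n_components > min(dim(X))) {
    stop("n_components exceeds the rank bound min(dim(X))")
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  X0 <- sweep(X, 2, x_mean); y0 <- y - y_mean
  p <- ncol(X); n <- nrow(X)
  S <- crossprod(X0, y0)                # p x 1 cross-covariance
  R <- matrix(0, p, n_components)       # weights
  TT <- matrix(0, n, n_components)      # scores
  P <- matrix(0, p, n_components)       # x loadings
  q <- numeric(n_components)            # y loadings
  V <- matrix(0, p, n_components)       # orthonormal basis for deflation
  for (a in seq_len(n_components)) {
    r <- S                               # univariate y: dominant direction
    t_sc <- X0 %*% r
    t_sc <- t_sc - mean(t_sc)
    nt <- sqrt(sum(t_sc^2))
    if (nt < .Machine$double.eps^0.5) {
      stop("rank-deficient predictors: cannot extract component ", a)
    }
    t_sc <- t_sc / nt; r <- r / nt
    p_a <- crossprod(X0, t_sc)
    q[a] <- crossprod(y0, t_sc)
    v <- p_a
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_a)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t_sc; P[, a] <- p_a; V[, a] <- v
  }
  coef <- R %*% q
  structure(list(coef = coef, intercept = y_mean - sum(x_mean * coef),
                 x_mean = x_mean, y_mean = y_mean, scores = TT,
                 weights = R, loadings = P, n_components = n_components),
            class = "plsr_fit")
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coef) + object$intercept
}

# Random partition of n items into `folds` near-equal groups.
fold_assignment <- function(n, folds) {
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  sample(rep(seq_len(folds), sizes))
}

#' Cross-validated PLSR decoding accuracy
#'
#' Repeated random `folds`-way splits of the movies; for each fold, the
#' model is fitted on the remaining movies and the held-out movies'
#' ratings are predicted; the Pearson correlation between predicted and
#' actual ratings per fold is the decoding accuracy, averaged over all
#' folds and iterations. Folds where the held-out ratings are constant
#' are skipped.
#'
#' @param X Matrix `movies x channels`.
#' @param y Mean rating per movie.
#' @param n_iter Random-split iterations (1000 at full scale).
#' @param folds Number of folds (3).
#' @param n_components PLS components (2).
#' @return List: `mean_r`, `fold_r` (all per-fold accuracies), `n_iter`,
#'   `folds`, `n_components`, `n_test` (held-out movies per fold).
#' @export
cv_decode <- function(X, y, n_iter = 1000, folds = 3, n_components = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * folds) stop("need at least ", 2 * folds, " movies")
  fold_r <- numeric(0)
  for (it in seq_len(n_iter)) {
    fa <- fold_assignment(n, folds)
    for (f in seq_len(folds)) {
      test <- fa == f
      if (length(unique(y[test])) < 2) next
      # degenerate training folds (constant response or an exactly null
      # cross-covariance on rank-deficient X) are skipped, not fatal
      fit <- tryCatch(
        plsr_fit(X[!test, , drop = FALSE], y[!test], n_components),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, X[test, , drop = FALSE])
      if (stats::sd(pred) == 0) next
      fold_r <- c(fold_r, stats::cor(pred, y[test]))
    }
  }
  list(mean_r = mean(fold_r), fold_r = fold_r, n_iter = n_iter,
       folds = folds, n_components = n_components,
       n_test = floor(n / folds))
}

#' Shuffle null for decoding accuracy
#'
#' Re-runs the full cross-validated decoding with the ratings randomly
#' permuted over movies, `n_shuffles` times, and ranks the observed mean
#' accuracy within the null: `p1 = (1 + #\{null >= observed\}) /
#' (1 + n_shuffles)`.
#'
#' @inheritParams cv_decode
#' @param n_shuffles Number of label permutations (10,000 at full scale).
#' @param inner_iter Split iterations inside each shuffle (and for the
#'   observed accuracy); scaled down by default to keep the nested scheme
#'   tractable.
#' @return List: `mean_r`, `p1`, `null`, plus the observed `cv` result.
#' @export
shuffle_null <- function(X, y, n_shuffles = 1000, inner_iter = 20,
                         folds = 3, n_components = 2) {
  obs <- cv_decode(X, y, n_iter = inner_iter, folds = folds,
                   n_components = n_components)
  null <- vapply(seq_len(n_shuffles), function(s) {
    cv_decode(X, sample(y), n_iter = inner_iter, folds = folds,
              n_components = n_components)$mean_r
  }, numeric(1))
  p1 <- (1 + sum(null >= obs$mean_r)) / (1 + n_shuffles)
  list(mean_r = obs$mean_r, p1 = p1, null = null, cv = obs)
}

#' Cross-stimulus decoding
#'
#' Trains the PLSR on two thirds of one stimulus type's movies and
#' predicts one third of the other type's movies, per iteration; the mean
#' per-fold Pearson r is the cross-decoding accuracy. An exclusion list
#' removes channels (e.g. the dual-coding sites) from both matrices
#' before decoding.
#'
#' @param X_train,y_train Movies x channels and ratings of the training
#'   stimulus type.
#' @param X_test,y_test Same for the tested stimulus type (identical
#'   channel set).
#' @param n_iter Iterations of the random-split scheme.
#' @param n_components PLS components.
#' @param exclude_channels Integer indices of channels to drop.
#' @param train_frac Fraction of training movies used per iteration (2/3).
#' @param test_frac Fraction of test movies predicted per iteration (1/3).
#' @return List as from [cv_decode()].
#' @export
cross_decode <- function(X_train, y_train, X_test, y_test, n_iter = 1000,
                         n_components = 2, exclude_channels = NULL,
                         train_frac = 2 / 3, test_frac = 1 / 3) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test)) stop("channel sets differ")
  if (!is.null(exclude_channels) && length(exclude_channels)) {
    if (length(exclude_channels) >= ncol(X_train)) {
      stop("exclusion removes all channels")
    }
    X_train <- X_train[, -exclude_channels, drop = FALSE]
    X_test <- X_test[, -exclude_channels, drop = FALSE]
  }
  n_tr <- nrow(X_train); n_te <- nrow(X_test)
  fold_r <- numeric(0)
  for (it in seq_len(n_iter)) {
    tr <- sample.int(n_tr, round(train_frac * n_tr))
    te <- sample.int(n_te, round(test_frac * n_te))
    if (length(unique(y_test[te])) < 2) next
    fit <- tryCatch(
      plsr_fit(X_train[tr, , drop = FALSE], y_train[tr], n_components),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred <- predict(fit, X_test[te, , drop = FALSE])
    if (stats::sd(pred) == 0) next
    fold_r <- c(fold_r, stats::cor(pred, y_test[te]))
  }
  list(mean_r = mean(fold_r), fold_r = fold_r, n_iter = n_iter,
       n_components = n_components)
}

#' Movie-level activity pattern and rating targets
#'
#' Averages a per-trial, per-channel activity measure (e.g. broadband
#' power averaged over the early or late period) over the presentations
#' of each movie of one stimulus type, and pairs it with the movies' mean
#' ratings - the inputs to the pattern-decoding analyses.
#'
#' @param period_avg Matrix `trials x channels` (see [period_average()]),
#'   rows aligned with `trial_meta`.
#' @param trial_meta Data frame with per-trial `stimulus` and `movie`.
#' @param ratings A `rating_table` giving the rating of every trial and
#'   patient (movie means are taken across patients and presentations).
#' @param stimulus Stimulus type to extract.
#' @return List: `X` (`movies x channels`), `y` (mean rating per movie),
#'   `movies`.
#' @export
movie_pattern_matrix <- function(period_avg, trial_meta, ratings,
                                 stimulus = c("Hand", "Face")) {
  stimulus <- match.arg(stimulus)
  stopifnot(nrow(period_avg) == nrow(trial_meta))
  sel <- trial_meta$stimulus == stimulus
  movies <- sort(unique(trial_meta$movie[sel]))
  X <- t(vapply(movies, function(m) {
    colMeans(period_avg[sel & trial_meta$movie == m, , drop = FALSE],
             na.rm = TRUE)
  }, numeric(ncol(period_avg))))
  mm <- movie_mean_ratings(ratings)
  mm <- mm[mm$stimulus == stimulus, ]
  list(X = X, y = mm$mean_rating[match(movies, mm$movie)], movies = movies)
}

#' Shuffle null for cross-stimulus decoding
#'
#' @inheritParams cross_decode
#' @param n_shuffles Label permutations of the *test* ratings.
#' @param inner_iter Iterations per shuffle.
#' @return List: `mean_r`, `p1`, `null`.
#' @export
cross_decode_null <- function(X_train, y_train, X_test, y_test,
                              n_shuffles = 1000, inner_iter = 20,
                              n_components = 2, exclude_channels = NULL) {
  obs <- cross_decode(X_train, y_train, X_test, y_test, n_iter = inner_iter,
                      n_components = n_components,
                      exclude_channels = exclude_channels)
  null <- vapply(seq_len(n_shuffles), function(s) {
    cross_decode(X_train, sample(y_train), X_test, sample(y_test),
                 n_iter = inner_iter, n_components = n_components,
                 exclude_channels = exclude_channels)$mean_r
  }, numeric(1))
  p1 <- (1 + sum(null >= obs$mean_r)) / (1 + n_shuffles)
  list(mean_r = obs$mean_r, p1 = p1, null = null)
}
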