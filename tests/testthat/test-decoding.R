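test_that("PLS1 weights align with the cross-covariance direction", {
  set.seed(201)
  # 5 x 3 toy: 1-component weights parallel to X0' y0 (SVD oracle)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  fit <- plsr_fit(X, y, n_components = 1)
  X0 <- scale(X, scale = FALSE); y0 <- y - mean(y)
  sv <- svd(crossprod(X0, matrix(y0)))
  w <- fit$weights[, 1] / sqrt(sum(fit$weights[, 1]^2))
  expect_equal(abs(sum(w * sv$u[, 1])), 1, tolerance = 1e-8)
  # y exactly linear in the single predictor: training predictions exact
  x1 <- matrix(rnorm(8), 8, 1)
  fit1 <- plsr_fit(x1, drop(3 * x1 + 2), n_components = 1)
  expect_equal(predict(fit1, x1), drop(3 * x1 + 2), tolerance = 1e-8)
  # permutation equivariance of coefficients
  X2 <- matrix(rnorm(40), 10, 4); y2 <- rnorm(10)
  f_a <- plsr_fit(X2, y2, 2)
  perm <- c(3, 1, 4, 2)
  f_b <- plsr_fit(X2[, perm], y2, 2)
  expect_equal(drop(f_b$coef), drop(f_a$coef)[perm], tolerance = 1e-10)
  expect_error(plsr_fit(X, y, n_components = 4), "n_components")
})

test_that("PLS predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(202)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("ch", 1:8)))
  y <- drop(X %*% rnorm(8) + rnorm(30))
  fit <- plsr_fit(X, y, n_components = 2)
  mo <- mixOmics::pls(X, y, ncomp = 2, scale = FALSE, mode = "regression")
  pred_mo <- predict(mo, X)$predict[, 1, 2]
  expect_equal(unname(predict(fit, X)), unname(pred_mo), tolerance = 1e-6)
})

test_that("cross-validated decoding is deterministic and accurate on clean data", {
  set.seed(203)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- drop(X %*% c(2, -1, 0, 0, 0, 0))   # noiseless linear rule
  set.seed(9); a <- cv_decode(X, y, n_iter = 20)
  set.seed(9); b <- cv_decode(X, y, n_iter = 20)
  expect_identical(a$mean_r, b$mean_r)
  # full-rank components recover the linear rule exactly; the 2-component
  # default still decodes nearly perfectly
  full <- cv_decode(X, y, n_iter = 20, n_components = 6)
  expect_gt(full$mean_r, 0.99)
  expect_gt(a$mean_r, 0.9)
  expect_equal(a$n_test, 10)
  # shuffled labels fall inside the null band
  set.seed(10)
  ys <- sample(y)
  null <- shuffle_null(X, ys, n_shuffles = 100, inner_iter = 5)
  expect_gt(null$p1, 0.05)
  expect_lt(abs(mean(null$null)), 0.1)
})

test_that("shuffle null p1 is extreme when observed tops the null", {
  set.seed(204)
  X <- matrix(rnorm(24 * 4), 24, 4)
  y <- drop(X %*% c(1, 1, 0, 0))
  out <- shuffle_null(X, y, n_shuffles = 200, inner_iter = 5)
  expect_equal(out$p1, 1 / 201, tolerance = 2 / 201)
})

test_that("cross-decoding transfers only through shared channels", {
  set.seed(205)
  n_mov <- 30; n_shared <- 4; n_excl <- 8
  y_hand <- runif(n_mov, 1, 4); y_face <- runif(n_mov, 1, 4)
  shared_h <- outer(y_hand, rnorm(n_shared, 1, 0.1)) + matrix(rnorm(n_mov * n_shared, sd = 0.4), n_mov)
  shared_f <- outer(y_face, rnorm(n_shared, 1, 0.1)) + matrix(rnorm(n_mov * n_shared, sd = 0.4), n_mov)
  excl_h <- outer(y_hand, rnorm(n_excl, 1, 0.1)) + matrix(rnorm(n_mov * n_excl, sd = 0.4), n_mov)
  excl_f <- matrix(rnorm(n_mov * n_excl, sd = 0.4), n_mov)   # face channels carry nothing
  X_hand <- cbind(shared_h, excl_h)
  X_face <- cbind(shared_f, excl_f)
  res <- cross_decode(X_hand, y_hand, X_face, y_face, n_iter = 100)
  expect_gt(res$mean_r, 0.4)
  # removing the shared channels collapses the transfer
  res2 <- cross_decode(X_hand, y_hand, X_face, y_face, n_iter = 100,
                       exclude_channels = seq_len(n_shared))
  expect_lt(res2$mean_r, 0.2)
  # within-type decoding unaffected by excluding signal-free channels
  w1 <- cv_decode(X_hand, y_hand, n_iter = 50)
  w2 <- cv_decode(X_hand[, 1:(n_shared + n_excl - 2)], y_hand, n_iter = 50)
  expect_equal(w1$mean_r, w2$mean_r, tolerance = 0.1)
  expect_error(cross_decode(X_hand, y_hand, X_face, y_face,
                            exclude_channels = 1:12), "all channels")
})

test_that("held-out movies never contribute to fitting", {
  set.seed(206)
  # adversarial audit: make one movie an extreme outlier; if it leaked into
  # training, predictions of the other movies would be dragged toward it
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- drop(X %*% c(1, 1, 1))
  audit_fit <- function() {
    fa <- insulacoder:::fold_assignment(12, 3)
    expect_equal(sort(unique(fa)), 1:3)
    expect_equal(as.vector(table(fa)), rep(4, 3))
    for (f in 1:3) {
      fit <- plsr_fit(X[fa != f, , drop = FALSE], y[fa != f], 2)
      # coefficients must be identical whatever the held-out block contains
      X_mod <- X; X_mod[fa == f, ] <- 1e6
      fit2 <- plsr_fit(X_mod[fa != f, , drop = FALSE], y[fa != f], 2)
      expect_identical(fit$coef, fit2$coef)
    }
  }
  audit_fit()
})

test_that("decoding accuracy grows with injected effect gain", {
  set.seed(207)
  acc <- vapply(c(0.1, 0.5, 1.5), function(g) {
    mean(replicate(10, {
      y <- runif(30, 1, 4)
      X <- outer(y, rep(g, 5)) + matrix(rnorm(150), 30, 5)
      cv_decode(X, y, n_iter = 10)$mean_r
    }))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})
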