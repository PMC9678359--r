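# Nonparametric null distributions: circular-shift cluster correction,
# condition-shuffle paired cluster test, and the patient-stratified
# whole-brain resampling null.

# Label 4-connected components of a logical matrix. Works on the sparse
# set of TRUE cells (union-find), so large mostly-FALSE grids stay cheap.
label_clusters <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  parent <- seq_along(idx)
  pos <- match(seq_len(length(mask)), idx)   # cell -> rank among TRUE cells
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  rows <- (idx - 1L) %% nr + 1L
  for (j in seq_along(idx)) {
    cell <- idx[j]
    if (rows[j] > 1L && !is.na(pos[cell - 1L])) union_(j, pos[cell - 1L])
    if (cell > nr && !is.na(pos[cell - nr])) union_(j, pos[cell - nr])
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# One-sample t statistics of channel values vs 0, per grid point.
# x: channels x points matrix; returns list(t, p2).
pointwise_t <- function(x) {
  n <- colSums(is.finite(x))
  m <- colMeans(x, na.rm = TRUE)
  s2 <- (colSums(x^2, na.rm = TRUE) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  t <- m / sqrt(s2 / n)
  p2 <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  list(t = t, p2 = p2)
}

# Largest positive and most negative cluster sums only - the fast path
# used inside permutation iterations (no per-cluster bookkeeping).
cluster_max_sums <- function(t_map, p_map, cluster_alpha) {
  sig <- is.finite(p_map) & p_map < cluster_alpha
  pos_max <- 0; neg_max <- 0
  lab <- label_clusters(sig & t_map > 0)
  if (any(lab > 0L)) {
    sums <- rowsum(t_map[lab > 0L], lab[lab > 0L])
    pos_max <- max(sums)
  }
  lab <- label_clusters(sig & t_map < 0)
  if (any(lab > 0L)) {
    sums <- rowsum(t_map[lab > 0L], lab[lab > 0L])
    neg_max <- min(sums)
  }
  c(pos_max, neg_max)
}

# Given t/p maps on a freqs x times grid, extract signed clusters.
# Returns list(pos_max, neg_max, clusters data frame).
extract_clusters <- function(t_map, p_map, cluster_alpha, freqs, times) {
  sig_pos <- is.finite(p_map) & p_map < cluster_alpha & t_map > 0
  sig_neg <- is.finite(p_map) & p_map < cluster_alpha & t_map < 0
  out <- list(pos_max = 0, neg_max = 0, clusters = NULL)
  rows <- list()
  for (sign in c(1, -1)) {
    lab <- label_clusters(if (sign > 0) sig_pos else sig_neg)
    if (!any(lab > 0)) next
    for (cl in seq_len(max(lab))) {
      cells <- which(lab == cl, arr.ind = TRUE)
      cs <- sum(t_map[lab == cl])
      rows[[length(rows) + 1]] <- data.frame(
        sign = sign, sum_t = cs,
        freq_min = freqs[min(cells[, 1])], freq_max = freqs[max(cells[, 1])],
        time_min = times[min(cells[, 2])], time_max = times[max(cells[, 2])],
        n_points = nrow(cells))
    }
    sums <- vapply(seq_len(max(lab)), function(cl) sum(t_map[lab == cl]),
                   numeric(1))
    if (sign > 0) out$pos_max <- max(sums) else out$neg_max <- min(sums)
  }
  if (length(rows)) out$clusters <- do.call(rbind, rows)
  out
}

#' Circular-shift cluster test of intensity-coding maps
#'
#' Tests where (in frequency and time) the channel-wise intensity-coding
#' coefficients depart from zero, correcting over the grid with a
#' cluster-based permutation scheme. The observed statistic is the
#' per-point one-sample t of the channel r-values against zero; points
#' with two-tailed `p < cluster_alpha` form 4-connected clusters scored by
#' their summed t. The null rotates each channel's map circularly along
#' time by an independent uniform offset (one offset per channel per
#' iteration, shared across that channel's frequencies) - preserving each
#' channel's autocorrelation while destroying temporal alignment - and
#' records the largest positive and most negative cluster sums into two
#' null distributions. Cluster `p1 = (1 + #\{null >= observed\}) /
#' (1 + n_iter)`.
#'
#' @param coding_maps Array `channels x freqs x times` of correlation
#'   coefficients (a `channels x times` matrix is a one-frequency grid).
#' @param n_iter Shift iterations (1000 in the reference analysis).
#' @param cluster_alpha Two-tailed cluster-forming threshold.
#' @param freqs,times Optional axes for reporting cluster extents.
#' @return Object of class `cluster_result`: `clusters` (with per-cluster
#'   `p1`), `null_pos`, `null_neg`, `t_map`, `sig_mask`.
#' @export
circular_shift_cluster_test <- function(coding_maps, n_iter = 1000,
                                        cluster_alpha = 0.05,
                                        freqs = NULL, times = NULL) {
  if (length(dim(coding_maps)) == 2) {
    dim(coding_maps) <- c(dim(coding_maps)[1], 1, dim(coding_maps)[2])
  }
  stopifnot(length(dim(coding_maps)) == 3)
  n_ch <- dim(coding_maps)[1]; n_f <- dim(coding_maps)[2]
  n_t <- dim(coding_maps)[3]
  if (n_ch < 2) stop("need at least 2 channels")
  if (n_iter < 100) warning("fewer than 100 iterations: unstable p-values")
  if (is.null(freqs)) freqs <- seq_len(n_f)
  if (is.null(times)) times <- seq_len(n_t)
  flat <- matrix(coding_maps, n_ch, n_f * n_t)
  obs <- pointwise_t(flat)
  t_map <- matrix(obs$t, n_f, n_t)
  p_map <- matrix(obs$p2, n_f, n_t)
  obs_cl <- extract_clusters(t_map, p_map, cluster_alpha, freqs, times)
  null_pos <- numeric(n_iter); null_neg <- numeric(n_iter)
  shifted <- coding_maps
  for (it in seq_len(n_iter)) {
    offs <- sample.int(n_t, n_ch, replace = TRUE) - 1L
    for (ch in seq_len(n_ch)) {
      if (offs[ch] > 0) {
        ord <- c((n_t - offs[ch] + 1):n_t, 1:(n_t - offs[ch]))
        shifted[ch, , ] <- coding_maps[ch, , ord, drop = FALSE]
      } else {
        shifted[ch, , ] <- coding_maps[ch, , , drop = FALSE]
      }
    }
    ni <- pointwise_t(matrix(shifted, n_ch, n_f * n_t))
    mm <- cluster_max_sums(matrix(ni$t, n_f, n_t), matrix(ni$p2, n_f, n_t),
                           cluster_alpha)
    null_pos[it] <- mm[1]
    null_neg[it] <- mm[2]
  }
  finish_cluster_result(obs_cl, t_map, p_map, cluster_alpha, n_iter,
                        null_pos, null_neg, freqs, times)
}

finish_cluster_result <- function(obs_cl, t_map, p_map, cluster_alpha,
                                  n_iter, null_pos, null_neg, freqs, times) {
  clusters <- obs_cl$clusters
  if (!is.null(clusters)) {
    clusters$p1 <- ifelse(
      clusters$sign > 0,
      (1 + vapply(clusters$sum_t, function(s) sum(null_pos >= s), numeric(1))) /
        (1 + n_iter),
      (1 + vapply(clusters$sum_t, function(s) sum(null_neg <= s), numeric(1))) /
        (1 + n_iter))
  }
  structure(list(clusters = clusters, t_map = t_map, p_map = p_map,
                 sig_mask = is.finite(p_map) & p_map < cluster_alpha,
                 cluster_alpha = cluster_alpha, n_iterations = n_iter,
                 null_pos = null_pos, null_neg = null_neg,
                 freqs = freqs, times = times),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d iterations, cluster alpha %.3g\n",
              x$n_iterations, x$cluster_alpha))
  if (is.null(x$clusters)) {
    cat("  no supra-threshold cluster\n")
  } else {
    print(x$clusters[order(x$clusters$p1), ])
  }
  invisible(x)
}

#' Significant clusters at a family-wise level
#' @param x A `cluster_result`.
#' @param alpha Cluster-level one-tailed alpha.
#' @return The subset of `x$clusters` with `p1 <= alpha` (possibly empty).
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cluster_result"))
  if (is.null(x$clusters)) return(NULL)
  x$clusters[x$clusters$p1 <= alpha, , drop = FALSE]
}

# Per-channel per-point Spearman maps for a trial subset.
# bbp: trials x channels x points; returns channels x points.
subset_r_maps <- function(bbp, ratings, trials) {
  n_ch <- dim(bbp)[2]
  out <- matrix(NA_real_, n_ch, dim(bbp)[3])
  for (ch in seq_len(n_ch)) {
    out[ch, ] <- col_spearman(bbp[trials, ch, , drop = TRUE], ratings[trials])
  }
  out
}

#' Condition-shuffle cluster test of Hand-vs-Face coding differences
#'
#' Compares the intensity-coding time(-frequency) profiles between two
#' stimulus conditions. Observed statistic: per grid point, a paired t
#' across channels of `r_cond1 - r_cond2`. The null reassigns trials to
#' conditions at random (preserving group sizes) and recomputes both
#' r-maps each iteration; cluster logic as in
#' [circular_shift_cluster_test()].
#'
#' @param bbp Array `trials x channels x times` of broadband power.
#' @param ratings Per-trial ratings.
#' @param condition Per-trial factor with exactly two levels; the contrast
#'   is `levels[1] - levels[2]`.
#' @param n_iter Shuffle iterations.
#' @param cluster_alpha Cluster-forming threshold.
#' @param times Optional time axis.
#' @return A `cluster_result` (grid has one frequency row).
#' @export
condition_shuffle_cluster_test <- function(bbp, ratings, condition,
                                           n_iter = 1000,
                                           cluster_alpha = 0.05,
                                           times = NULL) {
  stopifnot(length(dim(bbp)) == 3)
  if (n_iter < 1) stop("n_iter must be positive")
  condition <- as.factor(condition)
  lev <- levels(condition)
  if (length(lev) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 5)) stop("both conditions need >= 5 trials")
  if (diff(table(condition)) != 0) {
    message("unbalanced conditions: ", paste(table(condition), collapse = " vs "))
  }
  n_t <- dim(bbp)[3]
  if (is.null(times)) times <- seq_len(n_t)
  i1 <- which(condition == lev[1]); i2 <- which(condition == lev[2])
  diff_map <- function(a, b) {
    subset_r_maps(bbp, ratings, a) - subset_r_maps(bbp, ratings, b)
  }
  d_obs <- diff_map(i1, i2)
  obs <- pointwise_t(d_obs)
  t_map <- matrix(obs$t, 1, n_t); p_map <- matrix(obs$p2, 1, n_t)
  obs_cl <- extract_clusters(t_map, p_map, cluster_alpha, 1, times)
  null_pos <- numeric(n_iter); null_neg <- numeric(n_iter)
  all_i <- c(i1, i2)
  for (it in seq_len(n_iter)) {
    perm <- sample(all_i)
    a <- perm[seq_along(i1)]; b <- perm[-seq_along(i1)]
    ni <- pointwise_t(diff_map(a, b))
    mm <- cluster_max_sums(matrix(ni$t, 1, n_t), matrix(ni$p2, 1, n_t),
                           cluster_alpha)
    null_pos[it] <- mm[1]
    null_neg[it] <- mm[2]
  }
  finish_cluster_result(obs_cl, t_map, p_map, cluster_alpha, n_iter,
                        null_pos, null_neg, 1, times)
}

#' Patient-stratified whole-brain resampling null
#'
#' Asks whether the insular coding coefficients are enriched relative to
#' electrodes anywhere in the brain. Each iteration draws, from every
#' patient's whole-brain pool, as many r-values as that patient
#' contributes insular channels, pools them, and computes a one-sample t
#' against zero; the observed insular t is ranked against this null.
#'
#' @param insula_r List (one element per patient) of insular coding
#'   coefficients.
#' @param brain_r List (same patients) of whole-brain coefficients; each
#'   pool must be at least as large as the patient's insular count.
#' @param n_iter Resampling iterations (100,000 in the reference analysis).
#' @return List: `t_obs`, `p1`, `null_t`, `draw_counts`.
#' @export
whole_brain_resampling_null <- function(insula_r, brain_r, n_iter = 100000) {
  stopifnot(length(insula_r) == length(brain_r))
  counts <- lengths(insula_r)
  if (any(lengths(brain_r) < counts)) {
    stop("whole-brain pool smaller than insular count for some patient")
  }
  all_ins <- unlist(insula_r)
  t_of <- function(v) {
    m <- mean(v); m / (stats::sd(v) / sqrt(length(v)))
  }
  t_obs <- t_of(all_ins)
  null_t <- vapply(seq_len(n_iter), function(it) {
    t_of(unlist(mapply(function(pool, k) pool[sample.int(length(pool), k)],
                       brain_r, counts, SIMPLIFY = FALSE)))
  }, numeric(1))
  p1 <- (1 + sum(null_t >= t_obs)) / (1 + n_iter)
  list(t_obs = t_obs, p1 = p1, null_t = null_t, draw_counts = counts)
}
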