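#' The fixed spectral feature grid
#'
#' 145 frequency bins uniformly spanning 5-40 Hz (step ~0.243 Hz), pinned
#' to the channels-by-frequencies feature dimension used throughout.
#'
#' @return numeric vector of length 145.
#' @export
feature_freq_grid <- function() seq(5, 40, length.out = 145)

## Welch-averaged one-sided periodogram of one channel. Hann windows,
## 50% overlap; density normalization so sum(psd) * df ~ variance.
welch_psd <- function(x, fs, window_s = 2) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("epoch shorter than one Welch window")
  step <- floor(nwin / 2)
  starts <- seq(1, length(x) - nwin + 1, by = max(step, 1))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1)) # hann
  segs <- vapply(starts, function(s) x[s:(s + nwin - 1)] * w,
                 numeric(nwin))
  S <- stats::mvfft(segs)
  p <- rowMeans(Mod(S)^2)
  u <- sum(w^2) * fs
  half <- floor(nwin / 2) + 1
  psd <- p[seq_len(half)] / u
  psd[2:(half - 1)] <- 2 * psd[2:(half - 1)] # one-sided
  list(freq = (seq_len(half) - 1) * fs / nwin, psd = psd)
}

#' Per-epoch channel-by-frequency power spectra in dB
#'
#' Welch periodogram (2-s hann windows, 50% overlap; a 1-s epoch uses a
#' single window) per epoch and channel, converted to dB (10 log10) and
#' linearly interpolated onto the fixed 145-bin 5-40 Hz grid.
#'
#' @param epochs an `epoch_set` from [epoch_by_labels()].
#' @param window_s Welch window length (s); capped at the epoch length.
#' @return a `spectral_matrix`: list with `power_db` (epochs x channels x
#'   145), `freq_grid`, `label`, `start_s`, `fly_id`, `channel_ids`.
#' @export
epoch_spectrum <- function(epochs, window_s = 2) {
  dims <- dim(epochs$epochs)
  grid <- feature_freq_grid()
  if (epochs$epoch_s < 1) stop("epoch shorter than one Welch window")
  window_s <- min(window_s, epochs$epoch_s)
  power_db <- array(0, dim = c(dims[1], dims[2], length(grid)))
  for (e in seq_len(dims[1])) {
    for (ch in seq_len(dims[2])) {
      w <- welch_psd(epochs$epochs[e, ch, ], epochs$fs, window_s)
      db <- 10 * log10(pmax(w$psd, 1e-300))
      power_db[e, ch, ] <- stats::approx(w$freq, db, xout = grid,
                                         rule = 2)$y
    }
  }
  out <- list(power_db = power_db, freq_grid = grid, label = epochs$label,
              start_s = epochs$start_s, fly_id = epochs$fly_id,
              channel_ids = epochs$channel_ids)
  class(out) <- "spectral_matrix"
  out
}

#' Per-fly condition difference and Cohen's d map
#'
#' For each fly: mean spectrum of condition A minus mean spectrum of
#' condition B (dB). Cohen's d per (channel, frequency) cell is the
#' across-fly mean difference divided by the across-fly SD of the
#' differences.
#'
#' @param spectra list of `spectral_matrix`, one per fly.
#' @param cond_a,cond_b condition labels.
#' @param min_trials per-fly minimum epochs under each condition for the
#'   fly to be included.
#' @return list with `diff` (flies x channels x freqs array), `d`
#'   (channels x freqs), `flies` (ids included).
#' @export
condition_contrast <- function(spectra, cond_a, cond_b, min_trials = 10) {
  if (inherits(spectra, "spectral_matrix")) spectra <- list(spectra)
  diffs <- list(); ids <- character(0)
  for (sm in spectra) {
    na <- sum(sm$label == cond_a); nb <- sum(sm$label == cond_b)
    if (na < min_trials || nb < min_trials) next
    ma <- apply(sm$power_db[sm$label == cond_a, , , drop = FALSE], c(2, 3), mean)
    mb <- apply(sm$power_db[sm$label == cond_b, , , drop = FALSE], c(2, 3), mean)
    diffs[[length(diffs) + 1]] <- ma - mb
    ids <- c(ids, sm$fly_id)
  }
  if (!length(diffs)) stop("no fly has both conditions at the trial minimum")
  diff <- array(0, dim = c(length(diffs), dim(diffs[[1]])))
  for (i in seq_along(diffs)) diff[i, , ] <- diffs[[i]]
  m <- apply(diff, c(2, 3), mean)
  s <- apply(diff, c(2, 3), stats::sd)
  d <- ifelse(s > 0, m / s, 0)
  list(diff = diff, d = d, flies = ids)
}

## 4-connected component labeling on a logical matrix by iterative
## minimum-label propagation (vectorized shifts; converges in at most
## nrow+ncol sweeps).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    nr <- nrow(lab); nc <- ncol(lab)
    up <- rbind(lab[-1, , drop = FALSE], rep(0L, nc))
    dn <- rbind(rep(0L, nc), lab[-nr, , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], rep(0L, nr))
    rt <- cbind(rep(0L, nr), lab[, -nc, drop = FALSE])
    for (m in list(up, dn, lf, rt)) {
      take <- mask & m > 0 & (nb == 0 | m < nb)
      nb[take] <- m[take]
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

## Observed or permuted one-sample t map from a flies x cells matrix with
## fixed column sums of squares (sign flips leave ssq unchanged).
t_from_means <- function(m, ssq, n) {
  varr <- (ssq - n * m^2) / (n - 1)
  varr[varr < 0] <- 0
  tt <- m / sqrt(varr / n)
  tt[!is.finite(tt)] <- 0
  tt
}

max_cluster_mass <- function(tmat, thr) {
  mm <- 0
  for (sgn in c(1, -1)) {
    mask <- sgn * tmat > thr
    if (!any(mask)) next
    lab <- label_components(mask)
    mass <- tapply(abs(tmat)[mask], lab[mask], sum)
    mm <- max(mm, mass)
  }
  mm
}

#' Cluster-based permutation test on per-fly difference maps
#'
#' One-sample t per (channel, frequency) cell across flies; cells with
#' |t| above the two-sided alpha threshold (df = n-1) are joined into
#' clusters by 4-connectivity on the channel-by-frequency lattice
#' (positive and negative cells clustered separately); cluster mass is the
#' sum of |t|. The null is built by flipping the sign of whole fly rows:
#' all 2^n flips when n <= `enumerate_max`, otherwise `n_perm` random
#' flips. Cluster p is the fraction of null maximum masses greater than or
#' equal to the observed mass (ties count, conservative).
#'
#' @param diff flies x channels x freqs array of per-fly differences (or
#'   the list from [condition_contrast()]).
#' @param alpha cluster-forming and reporting alpha.
#' @param n_perm number of random sign flips when enumeration is off.
#' @param enumerate_max largest n for full enumeration.
#' @return a `cluster_test`: list with `t_map`, `clusters` (list of logical
#'   masks), `cluster_p`, `cluster_mass`, `n_permutations`, `alpha`,
#'   `null_max_mass`.
#' @export
cluster_permutation <- function(diff, alpha = 0.05, n_perm = 4096,
                                enumerate_max = 14) {
  if (is.list(diff) && !is.null(diff$diff)) diff <- diff$diff
  n <- dim(diff)[1]
  if (n < 5) stop("need at least 5 flies")
  n_ch <- dim(diff)[2]; n_f <- dim(diff)[3]
  X <- matrix(diff, nrow = n) # flies x (ch*freq), column-major cells
  if (any(apply(X, 2, stats::sd) == 0)) {
    warning("zero variance in some cells: t set to 0 there")
  }
  ssq <- colSums(X^2)
  thr <- stats::qt(1 - alpha / 2, df = n - 1)

  t_obs <- matrix(t_from_means(colMeans(X), ssq, n), n_ch, n_f)
  clusters <- list(); masses <- numeric(0)
  for (sgn in c(1, -1)) {
    mask <- sgn * t_obs > thr
    if (!any(mask)) next
    lab <- label_components(mask)
    for (k in seq_len(max(lab))) {
      cl <- lab == k
      clusters[[length(clusters) + 1]] <- cl
      masses <- c(masses, sum(abs(t_obs)[cl]))
    }
  }

  if (n <= enumerate_max) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    signs <- with_seed(n_perm + n, {
      rbind(rep(1, n),
            matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                   ncol = n))
    })
  }
  means <- (signs %*% X) / n
  null_max <- numeric(nrow(signs))
  for (p in seq_len(nrow(signs))) {
    tp <- matrix(t_from_means(means[p, ], ssq, n), n_ch, n_f)
    null_max[p] <- max_cluster_mass(tp, thr)
  }
  # ties count as >= (conservative); the tolerance absorbs float summation
  # order so the identity flip always ties its own cluster
  cluster_p <- vapply(masses, function(m) mean(null_max >= m - 1e-9),
                      numeric(1))

  out <- list(t_map = t_obs, clusters = clusters, cluster_p = cluster_p,
              cluster_mass = masses, n_permutations = nrow(signs),
              alpha = alpha, null_max_mass = null_max)
  class(out) <- "cluster_test"
  out
}

#' Significant clusters of a cluster test
#'
#' @param test a `cluster_test`.
#' @param alpha significance level (defaults to the test's alpha).
#' @return list of logical channel x frequency masks.
#' @export
significant_clusters <- function(test, alpha = test$alpha) {
  test$clusters[test$cluster_p < alpha]
}

#' Within-cluster signed post hoc summary
#'
#' Mean per-fly difference within the cluster mask, its sign, and a
#' one-sample t summary; used to state the direction of a significant
#' cluster.
#'
#' @param diff flies x channels x freqs array (or contrast list).
#' @param cluster_mask logical channels x freqs mask.
#' @return list with `per_fly_mean`, `mean`, `sign` ("positive",
#'   "negative" or "undetermined"), `t`, `p`.
#' @export
cluster_sign_posthoc <- function(diff, cluster_mask) {
  if (is.list(diff) && !is.null(diff$diff)) diff <- diff$diff
  if (!any(cluster_mask)) stop("empty cluster mask")
  n <- dim(diff)[1]
  per_fly <- vapply(seq_len(n),
                    function(i) mean(diff[i, , ][cluster_mask]), numeric(1))
  tt <- stats::t.test(per_fly)
  sgn <- if (tt$p.value < 0.05) {
    if (mean(per_fly) > 0) "positive" else "negative"
  } else "undetermined"
  list(per_fly_mean = per_fly, mean = mean(per_fly), sign = sgn,
       t = unname(tt$statistic), p = tt$p.value)
}
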