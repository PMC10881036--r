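make_epochs <- function(signals, fs = 250) {
  # signals: list of channels x samples matrices (one per epoch)
  arr <- array(0, dim = c(length(signals), nrow(signals[[1]]),
                          ncol(signals[[1]])))
  for (e in seq_along(signals)) arr[e, , ] <- signals[[e]]
  out <- list(epochs = arr, label = rep("x", length(signals)),
              start_s = seq_along(signals), epoch_s = ncol(signals[[1]]) / fs,
              fs = fs, fly_id = "f1", channel_ids = seq_len(nrow(signals[[1]])))
  class(out) <- "epoch_set"
  out
}

test_that("epoch spectra land on the 15 x 145 grid", {
  fs <- 250; t <- seq(1 / fs, 60, by = 1 / fs)
  sig <- matrix(stats::rnorm(15 * length(t)), 15, byrow = TRUE)
  sm <- epoch_spectrum(make_epochs(list(sig)))
  expect_equal(dim(sm$power_db), c(1, 15, 145))
  expect_equal(length(feature_freq_grid()), 145)
  expect_equal(range(feature_freq_grid()), c(5, 40))
  expect_true(all(diff(sm$freq_grid) > 0))
  expect_true(all(is.finite(sm$power_db)))
  short <- make_epochs(list(sig[, 1:100, drop = FALSE]))
  short$epoch_s <- 0.4
  expect_error(epoch_spectrum(short), "shorter than one Welch window")
})

test_that("doubling a sine's amplitude adds 6.02 dB at its bin", {
  fs <- 250; t <- seq(1 / fs, 60, by = 1 / fs)
  s1 <- matrix(sin(2 * pi * 10 * t), 1)
  s2 <- 2 * s1
  sm <- epoch_spectrum(make_epochs(list(s1, s2)))
  i10 <- which.min(abs(feature_freq_grid() - 10))
  expect_lt(abs((sm$power_db[2, 1, i10] - sm$power_db[1, 1, i10]) -
                  20 * log10(2)), 0.1)
})

test_that("white-noise spectra are flat across the grid", {
  fs <- 250
  set.seed(4)
  slopes <- vapply(1:5, function(i) {
    sig <- matrix(stats::rnorm(60 * fs), 1)
    sm <- epoch_spectrum(make_epochs(list(sig)))
    unname(stats::coef(stats::lm(sm$power_db[1, 1, ] ~ feature_freq_grid()))[2])
  }, numeric(1))
  expect_lt(max(abs(slopes)), 0.02) # dB per Hz
})

test_that("band power integrates to the time-domain variance", {
  fs <- 250
  set.seed(9)
  x <- flysleeplfp:::band_noise(60 * fs, fs, 5, 40)
  w <- flysleeplfp:::welch_psd(x, fs)
  df <- diff(w$freq)[1]
  expect_lt(abs(sum(w$psd) * df / stats::var(x) - 1), 0.05)
})

test_that("condition contrast matches a hand-coded two-pass oracle", {
  set.seed(6)
  spectra <- lapply(1:6, function(f) {
    arr <- array(stats::rnorm(20 * 4 * 145), dim = c(20, 4, 145))
    out <- list(power_db = arr, freq_grid = feature_freq_grid(),
                label = rep(c("a", "b"), each = 10), start_s = 1:20,
                fly_id = paste0("f", f), channel_ids = 1:4)
    class(out) <- "spectral_matrix"
    out
  })
  cc <- condition_contrast(spectra, "a", "b", min_trials = 10)
  # oracle: explicit loops
  diffs <- array(0, dim = c(6, 4, 145))
  for (f in 1:6) {
    sm <- spectra[[f]]
    for (ch in 1:4) for (k in 1:145) {
      diffs[f, ch, k] <- mean(sm$power_db[1:10, ch, k]) -
        mean(sm$power_db[11:20, ch, k])
    }
  }
  d_o <- matrix(0, 4, 145)
  for (ch in 1:4) for (k in 1:145) {
    v <- diffs[, ch, k]
    d_o[ch, k] <- mean(v) / stats::sd(v)
  }
  expect_lt(max(abs(cc$diff - diffs)), 1e-12)
  expect_lt(max(abs(cc$d - d_o)), 1e-12)
  # degenerate cases
  unit <- lapply(spectra, function(sm) {
    sm$power_db[sm$label == "a", , ] <- sm$power_db[sm$label == "b", , ] + 1
    sm
  })
  cc2 <- condition_contrast(unit, "a", "b", min_trials = 10)
  expect_true(all(abs(cc2$diff - 1) < 1e-12))
  same <- lapply(spectra, function(sm) {
    sm$power_db[sm$label == "a", , ] <- sm$power_db[sm$label == "b", , ]
    sm
  })
  cc3 <- condition_contrast(same, "a", "b", min_trials = 10)
  expect_true(all(cc3$diff == 0) && all(cc3$d == 0))
  # a fly below the trial minimum is excluded
  spectra[[1]]$label <- c(rep("a", 9), rep("b", 11))
  cc4 <- condition_contrast(spectra, "a", "b", min_trials = 10)
  expect_equal(dim(cc4$diff)[1], 5)
})

## Independent oracle: explicit sign-flip enumeration with igraph
## connected components on the 4-connected lattice.
oracle_cluster <- function(diff, alpha = 0.05) {
  n <- dim(diff)[1]; n_ch <- dim(diff)[2]; n_f <- dim(diff)[3]
  thr <- stats::qt(1 - alpha / 2, df = n - 1)
  cell_t <- function(d) {
    apply(d, c(2, 3), function(v) {
      s <- stats::sd(v)
      if (s == 0) 0 else mean(v) / (s / sqrt(n))
    })
  }
  lattice_components <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(list())
    g_edges <- c()
    key <- function(r, c) paste(r, c)
    present <- stats::setNames(seq_len(nrow(idx)), key(idx[, 1], idx[, 2]))
    for (i in seq_len(nrow(idx))) {
      for (d in list(c(1, 0), c(0, 1))) {
        nb <- key(idx[i, 1] + d[1], idx[i, 2] + d[2])
        if (!is.na(present[nb])) g_edges <- c(g_edges, i, present[[nb]])
      }
    }
    g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
    if (length(g_edges)) g <- igraph::add_edges(g, g_edges)
    comp <- igraph::components(g)
    lapply(seq_len(comp$no), function(k) idx[comp$membership == k, ,
                                             drop = FALSE])
  }
  max_mass <- function(tmat) {
    mm <- 0
    for (sgn in c(1, -1)) {
      comps <- lattice_components(sgn * tmat > thr)
      for (cells in comps) {
        mm <- max(mm, sum(abs(tmat[cells])))
      }
    }
    mm
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- vapply(seq_len(nrow(signs)), function(p) {
    d2 <- diff * array(rep(signs[p, ], n_ch * n_f), dim = dim(diff))
    max_mass(cell_t(d2))
  }, numeric(1))
  t_obs <- cell_t(diff)
  obs <- c()
  for (sgn in c(1, -1)) {
    comps <- lattice_components(sgn * t_obs > thr)
    for (cells in comps) obs <- c(obs, sum(abs(t_obs[cells])))
  }
  list(null_max = null_max,
       p = vapply(obs, function(m) mean(null_max >= m - 1e-9), numeric(1)))
}

test_that("enumerated sign-flip null equals the brute-force oracle", {
  set.seed(11)
  d <- array(stats::rnorm(6 * 4 * 10), dim = c(6, 4, 10))
  d[, 1:2, 3:6] <- d[, 1:2, 3:6] + 1.5
  ct <- cluster_permutation(d, n_perm = 64)
  orc <- oracle_cluster(d)
  expect_equal(sort(ct$null_max_mass), sort(orc$null_max), tolerance = 1e-9)
  expect_equal(sort(ct$cluster_p), sort(orc$p), tolerance = 1e-12)
})

test_that("cluster test controls the family-wise error on null data", {
  set.seed(12)
  any_sig <- vapply(1:40, function(i) {
    d <- array(stats::rnorm(8 * 6 * 20), dim = c(8, 6, 20))
    ct <- cluster_permutation(d)
    any(ct$cluster_p < 0.05)
  }, logical(1))
  expect_lte(sum(any_sig), 5) # binomial bound around 40 * 0.05
})

test_that("a broadband effect yields one cluster spanning all channels", {
  set.seed(13)
  d <- array(stats::rnorm(9 * 15 * 30), dim = c(9, 15, 30)) + 2
  ct <- cluster_permutation(d)
  sig <- significant_clusters(ct)
  expect_equal(length(sig), 1)
  expect_equal(sum(rowSums(sig[[1]]) > 0), 15)
})

test_that("a localized effect stays near its injected block", {
  set.seed(14)
  d <- array(stats::rnorm(8 * 15 * 40), dim = c(8, 15, 40))
  d[, 1:5, 30:40] <- d[, 1:5, 30:40] + 2.5
  ct <- cluster_permutation(d)
  sig <- significant_clusters(ct)
  expect_gte(length(sig), 1)
  main <- sig[[which.max(vapply(sig, sum, numeric(1)))]]
  # contained in a one-step dilation of the injected block
  block <- matrix(FALSE, 15, 40); block[1:5, 30:40] <- TRUE
  dil <- block
  dil[1:6, 29:40] <- TRUE
  expect_true(all(!main | dil))
  # and covers most of the block
  expect_gt(sum(main & block) / sum(block), 0.8)
})

test_that("cluster p is invariant to adjacency-preserving relabeling and scaling", {
  set.seed(15)
  d <- array(stats::rnorm(7 * 6 * 15), dim = c(7, 6, 15))
  d[, 2:4, 5:10] <- d[, 2:4, 5:10] + 1.8
  ct <- cluster_permutation(d)
  d_rev <- d[, rev(seq_len(6)), , drop = FALSE] # reversal preserves adjacency
  ct_rev <- cluster_permutation(d_rev)
  expect_equal(sort(ct$cluster_p), sort(ct_rev$cluster_p))
  # one-sample t is scale-free, so scaling every fly leaves p unchanged
  ct_sc <- cluster_permutation(d * 3)
  expect_equal(sort(ct_sc$cluster_p), sort(ct$cluster_p))
  expect_error(cluster_permutation(d[1:4, , , drop = FALSE]), "5 flies")
})

test_that("the within-cluster post hoc reports the effect sign", {
  set.seed(16)
  d <- array(stats::rnorm(8 * 5 * 10, mean = 1), dim = c(8, 5, 10))
  mask <- matrix(TRUE, 5, 10)
  ph <- cluster_sign_posthoc(d, mask)
  expect_equal(ph$sign, "positive")
  expect_length(ph$per_fly_mean, 8)
  # antisymmetric across flies: mean ~ 0, sign undetermined
  anti <- array(0, dim = c(8, 5, 10))
  for (f in 1:8) anti[f, , ] <- (-1)^f
  ph2 <- cluster_sign_posthoc(anti, mask)
  expect_lt(abs(ph2$mean), 1e-12)
  expect_equal(ph2$sign, "undetermined")
  expect_error(cluster_sign_posthoc(d, matrix(FALSE, 5, 10)), "empty")
})
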