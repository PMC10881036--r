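## FIR kernels are applied in the frequency domain with their linear phase
## removed (equivalent to shifting the symmetric kernel to zero delay), so
## filtering is exactly zero-phase with the designed magnitude response
## applied once.
fir_zerophase <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel) # odd, symmetric
  half <- (m - 1) / 2
  nfft <- stats::nextn(n + m - 1, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(kernel, rep(0, nfft - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  y[(half + 1):(half + n)]
}

## Hamming windowed-sinc FIR designs via signal::fir1.
bandpass_kernel <- function(fs, f_lo, f_hi, trans_lo = 0.5, trans_hi = 10) {
  # order from the narrower transition band (hamming: ~3.3 / (tb/fs) taps)
  taps <- ceiling(3.3 / (min(trans_lo, trans_hi) / fs))
  if (taps %% 2 == 0) taps <- taps + 1
  signal::fir1(taps - 1, c(f_lo, f_hi) / (fs / 2), type = "pass",
               window = signal::hamming(taps))
}

notch_kernel <- function(fs, f0 = 50, width = 2) {
  taps <- ceiling(3.3 / ((width / 2) / fs))
  if (taps %% 2 == 0) taps <- taps + 1
  signal::fir1(taps - 1, c(f0 - width / 2, f0 + width / 2) / (fs / 2),
               type = "stop", window = signal::hamming(taps))
}

#' Preprocess a raw multichannel LFP recording
#'
#' Resamples to `fs_target` (250 Hz), bandpass-filters 0.5-40 Hz with a
#' zero-phase hamming windowed-sinc FIR, and notch-filters 50-Hz line
#' noise. If the recording arrives as hourly segments (a list of matrices),
#' segments are joined with linear interpolation across the boundary
#' samples before filtering.
#'
#' @param raw channels x samples matrix, or a list of such matrices
#'   (hourly segments).
#' @param fs input sampling rate in Hz (must be >= 80 Hz).
#' @param fs_target output sampling rate (default 250 Hz).
#' @param f_lo,f_hi bandpass edges in Hz.
#' @param notch notch center frequency (NULL to skip).
#' @param clock_start carried through to the result.
#' @return an `lfp_recording`: list with `data` (channels x samples), `fs`,
#'   `channel_ids`, `clock_start`.
#' @export
preprocess_lfp <- function(raw, fs, fs_target = 250, f_lo = 0.5, f_hi = 40,
                           notch = 50, clock_start = "08:00") {
  if (fs < 2 * f_hi) stop("sampling rate too low for the requested band")
  if (is.list(raw) && !is.matrix(raw)) raw <- join_segments(raw)
  data <- raw
  if (fs != fs_target) {
    # anti-alias zero-phase FIR at 0.9 x target Nyquist, then resample the
    # continuous reconstruction on the new grid
    taps <- 2 * ceiling(3.3 / (0.1 * fs_target / fs) / 2) + 1
    aa <- signal::fir1(taps - 1, 0.9 * fs_target / fs, type = "low",
                       window = signal::hamming(taps))
    t_old <- (seq_len(ncol(data)) - 1) / fs
    t_new <- seq(0, max(t_old), by = 1 / fs_target)
    data <- t(apply(data, 1, function(ch) {
      stats::approx(t_old, fir_zerophase(ch, aa), xout = t_new)$y
    }))
    fs <- fs_target
  }
  kern <- bandpass_kernel(fs, f_lo, f_hi)
  if (!is.null(notch) && fs / 2 > notch) {
    # cascade the two zero-phase FIRs as a single combined kernel
    kern <- stats::convolve(kern, rev(notch_kernel(fs)), type = "open")
  }
  for (ch in seq_len(nrow(data))) {
    data[ch, ] <- fir_zerophase(data[ch, ], kern)
  }
  if (anyNA(data)) stop("NaNs after preprocessing")
  out <- list(data = data, fs = fs,
              channel_ids = seq_len(nrow(data)), clock_start = clock_start)
  class(out) <- "lfp_recording"
  out
}

## Join hourly segments, linearly interpolating over a short seam to avoid
## discontinuities at segment boundaries.
join_segments <- function(segments, seam = 5L) {
  out <- segments[[1]]
  for (k in seq_along(segments)[-1]) {
    nxt <- segments[[k]]
    n0 <- ncol(out)
    jump <- nxt[, 1] - out[, n0]
    ramp <- seq(0, 1, length.out = 2 * seam + 1)[-c(1, 2 * seam + 1)]
    seam_block <- out[, n0] + outer(jump, ramp)
    out <- cbind(out, seam_block, nxt)
  }
  out
}

#' Detect the polarity-reversal channel from a calibration recording
#'
#' Averages stimulus-locked responses (baseline-corrected by the 50 ms
#' preceding each onset), summarizes each channel by its mean deflection in
#' the 0-200 ms post-onset window, and returns the channel at the first
#' sign change of the across-channel evoked-amplitude profile (the neighbor
#' with the smaller absolute deflection). Calibration is considered valid
#' when the result falls in channels 11-13.
#'
#' @param cal list with `lfp` (16 x samples), `fs`, `stimulus_onsets` (s).
#' @return integer channel index.
#' @export
detect_polarity_reversal <- function(cal) {
  if (length(cal$stimulus_onsets) < 5) stop("need at least 5 stimulus onsets")
  fs <- cal$fs
  win <- round(0.2 * fs)
  base <- round(0.05 * fs)
  prof <- numeric(nrow(cal$lfp))
  for (ch in seq_len(nrow(cal$lfp))) {
    vals <- vapply(cal$stimulus_onsets, function(o) {
      i0 <- round(o * fs) + 1
      if (i0 + win > ncol(cal$lfp) || i0 - base < 1) return(NA_real_)
      mean(cal$lfp[ch, i0:(i0 + win)]) - mean(cal$lfp[ch, (i0 - base):(i0 - 1)])
    }, numeric(1))
    prof[ch] <- mean(vals, na.rm = TRUE)
  }
  s <- sign(prof)
  nz <- which(s != 0)
  flip_k <- which(s[nz[-length(nz)]] != s[nz[-1]])
  if (!length(flip_k) ||
      (length(nz) && all(s[nz] == s[nz[1]]))) {
    stop("no reversal found: evoked profile has no sign change")
  }
  cand <- nz[flip_k[1]]:nz[flip_k[1] + 1]
  as.integer(cand[which.min(abs(prof[cand]))])
}

#' Re-reference against the polarity-reversal channel
#'
#' Subtracts the reference channel from every other channel, dropping it
#' and leaving 15 channels. Original channel indices are preserved and the
#' printed group assignment is attached: central 1-5, middle 6-10,
#' peripheral 12-16. Refuses to run twice.
#'
#' @param lfp an `lfp_recording`.
#' @param reference_channel channel index 1-16.
#' @return a `referenced_lfp`: list with `data` (15 x samples), `fs`,
#'   `channel_ids` (original indices), `reference_channel`, `groups`.
#' @export
rereference <- function(lfp, reference_channel) {
  if (inherits(lfp, "referenced_lfp")) {
    stop("recording is already re-referenced; refusing a second application")
  }
  n_ch <- nrow(lfp$data)
  if (reference_channel < 1 || reference_channel > n_ch) {
    stop("reference channel out of range")
  }
  ref <- lfp$data[reference_channel, ]
  keep <- setdiff(seq_len(n_ch), reference_channel)
  data <- lfp$data[keep, , drop = FALSE] -
    matrix(ref, nrow = length(keep), ncol = length(ref), byrow = TRUE)
  out <- list(
    data = data, fs = lfp$fs, channel_ids = lfp$channel_ids[keep],
    reference_channel = as.integer(reference_channel),
    groups = list(central = 1:5, middle = 6:10, peripheral = 12:16),
    clock_start = lfp$clock_start
  )
  class(out) <- "referenced_lfp"
  out
}

#' Differential (bipolar) re-referencing
#'
#' Subtracts nearby channels from each other (`k+1 - k`), yielding 15
#' channels; used for the induced-sleep pipeline variant. Common-mode
#' signal cancels exactly.
#'
#' @param lfp an `lfp_recording` with 16 channels.
#' @return a `referenced_lfp` with 15 channels.
#' @export
differential_rereference <- function(lfp) {
  n_ch <- nrow(lfp$data)
  data <- lfp$data[-1, , drop = FALSE] - lfp$data[-n_ch, , drop = FALSE]
  out <- list(
    data = data, fs = lfp$fs, channel_ids = seq_len(n_ch - 1),
    reference_channel = NA_integer_,
    groups = list(central = 1:5, middle = 6:10, peripheral = 12:16),
    clock_start = lfp$clock_start
  )
  class(out) <- "referenced_lfp"
  out
}

#' Cut labeled intervals into fixed-length epochs
#'
#' Tiles each labeled interval with non-overlapping epochs of `epoch_s`
#' seconds starting at the interval onset; a tail shorter than `epoch_s` is
#' dropped. Conditions with fewer than `min_trials` epochs are excluded
#' (the defaults mirror the per-fly trial minima: 10 for 60-s epochs, 50
#' for 1-s epochs).
#'
#' @param lfp a `referenced_lfp` (or `lfp_recording`).
#' @param labels data.frame with `start_s`, `end_s`, and a label column
#'   (`stage` or `label`).
#' @param epoch_s epoch length in seconds.
#' @param min_trials minimum epochs per condition; `NULL` picks the printed
#'   default for `epoch_s`, use 0 to keep everything.
#' @param fly_id identifier stored on the result.
#' @return an `epoch_set`: list with `epochs` (epochs x channels x
#'   samples), `label`, `start_s`, `epoch_s`, `fs`, `fly_id`.
#' @export
epoch_by_labels <- function(lfp, labels, epoch_s = 60, min_trials = NULL,
                            fly_id = "fly01") {
  if (is.null(min_trials)) {
    min_trials <- if (epoch_s >= 60) 10L else if (epoch_s <= 1) 50L else 0L
  }
  lab_col <- if ("stage" %in% names(labels)) "stage" else "label"
  fs <- lfp$fs
  len <- round(epoch_s * fs)
  n <- ncol(lfp$data)
  starts <- numeric(0); labs <- character(0)
  for (i in seq_len(nrow(labels))) {
    k <- floor((labels$end_s[i] - labels$start_s[i]) / epoch_s)
    if (k < 1) next
    s0 <- labels$start_s[i] + (seq_len(k) - 1) * epoch_s
    ok <- round(s0 * fs) + len <= n
    starts <- c(starts, s0[ok])
    labs <- c(labs, rep(labels[[lab_col]][i], sum(ok)))
  }
  if (!length(starts)) {
    warning("no interval long enough for the requested epoch length")
  }
  tab <- table(labs)
  keep_lab <- names(tab)[tab >= min_trials]
  keep <- labs %in% keep_lab
  starts <- starts[keep]; labs <- labs[keep]
  epochs <- array(0, dim = c(length(starts), nrow(lfp$data), len))
  for (e in seq_along(starts)) {
    i0 <- round(starts[e] * fs) + 1
    epochs[e, , ] <- lfp$data[, i0:(i0 + len - 1)]
  }
  out <- list(epochs = epochs, label = labs, start_s = starts,
              epoch_s = epoch_s, fs = fs, fly_id = fly_id,
              channel_ids = lfp$channel_ids)
  class(out) <- "epoch_set"
  out
}

#' Localize electrode sites from dye points
#'
#' Fits the probe track as the first principal component of the dye point
#' cloud, projects the innermost dye point onto that line, and places the
#' 16 sites at 25-um intervals outward along the track. The eigenvector
#' sign is chosen so site index increases toward the periphery (away from
#' the innermost point).
#'
#' @param dye_points n x 3 matrix of dye coordinates (um).
#' @param spacing inter-site spacing in um.
#' @param n_sites number of electrode sites.
#' @return an `electrode_track`: list with `site_coords` (n_sites x 3),
#'   `eigenvector` (unit 3-vector), `spacing`.
#' @export
localize_electrodes <- function(dye_points, spacing = 25, n_sites = 16) {
  dye_points <- as.matrix(dye_points)
  if (nrow(dye_points) < 2) stop("need at least 2 dye points")
  if (max(stats::dist(dye_points)) < 1e-9) stop("dye points are coincident")
  ctr <- colMeans(dye_points)
  pc <- stats::prcomp(dye_points, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  proj <- as.numeric((dye_points - matrix(ctr, nrow(dye_points), 3,
                                          byrow = TRUE)) %*% v)
  # innermost = the track endpoint lying deeper (farther from the cloud
  # centroid, a geometric and therefore order- and rotation-invariant
  # rule); orient v from there outward so site index grows peripherally
  if (abs(min(proj)) < abs(max(proj))) {
    v <- -v
    proj <- -proj
  }
  inner <- ctr + min(proj) * v
  sites <- t(vapply(seq_len(n_sites) - 1,
                    function(k) inner + k * spacing * v, numeric(3)))
  out <- list(site_coords = sites, eigenvector = v, spacing = spacing)
  class(out) <- "electrode_track"
  out
}
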