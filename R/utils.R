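# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Session-lifetime cache (used by the test suite to share expensive
## synthetic cohorts across test files).
.pkg_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .pkg_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .pkg_cache)
  }
  get(key, envir = .pkg_cache, inherits = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream. All stochastic operations in this package funnel
#' through explicit seeds via this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Clock handling: clock_start is "HH:MM" time of day at recording onset.
parse_clock <- function(clock_start) {
  parts <- as.numeric(strsplit(clock_start, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || anyNA(parts)) {
    stop("clock_start must be 'HH:MM', got ", clock_start)
  }
  parts[1] * 3600 + parts[2] * 60
}

## Time of day (seconds in [0, 86400)) for recording times `t_s`.
time_of_day <- function(t_s, clock_start) {
  (parse_clock(clock_start) + t_s) %% 86400
}

## Lights on 8 a.m. to 8 p.m.
is_day <- function(t_s, clock_start) {
  tod <- time_of_day(t_s, clock_start)
  tod >= 8 * 3600 & tod < 20 * 3600
}

## Band-limited unit-variance Gaussian noise via frequency-domain synthesis.
band_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs) # two-sided -> folded frequency
  keep <- freqs >= f_lo & freqs <= f_hi
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

## 1/f^alpha colored noise (power spectrum ~ f^-alpha), unit variance.
pink_noise <- function(n, alpha = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- c(1, seq_len(n - 1)) # avoid division by zero at DC
  k <- pmin(k, n - k + 1)
  X <- X * k^(-alpha / 2)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

## Fill a per-sample (or per-second) vector from labeled intervals.
## intervals: data.frame(start_s, end_s); values recycled. Half-open [start, end).
fill_intervals <- function(n, rate, intervals, values, default) {
  out <- rep(default, n)
  for (i in seq_len(nrow(intervals))) {
    a <- floor(intervals$start_s[i] * rate) + 1
    b <- ceiling(intervals$end_s[i] * rate)
    a <- max(a, 1L)
    b <- min(b, n)
    if (a <= b) out[a:b] <- values[i]
  }
  out
}

## Runs of equal values: data.frame(value, start, end, length) with 1-based
## inclusive indices.
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(
    value = r$values, start = ends - r$lengths + 1, end = ends,
    length = r$lengths
  )
}

stopifnot_scalar <- function(x, field, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("invalid config field '", field, "': must be a finite number")
  }
  if (positive && x <= 0) {
    stop("invalid config field '", field, "': must be > 0")
  }
  invisible(x)
}
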