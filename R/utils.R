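# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# filtfilt with even-reflection end padding (signal::filtfilt does not pad,
# which leaves large transients at both ends; symmetric mirroring keeps the
# edge derivative of a resting signal near zero).
filtfilt_pad <- function(bf, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  xp <- c(x[(p + 1L):2], x, x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)]
}

# Zero-phase Butterworth low-pass.
lowpass_zp <- function(x, fs, fc, order = 2) {
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  filtfilt_pad(bf, as.numeric(x), as.integer(ceiling(fs / 2)))
}

# Zero-phase Butterworth band-pass.
bandpass_zp <- function(x, fs, lo, hi, order = 2) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  filtfilt_pad(bf, as.numeric(x), as.integer(ceiling(fs / 2)))
}

# Central-difference derivative (one-sided at the ends).
deriv_c <- function(x, fs) {
  pracma::gradient(as.numeric(x), 1 / fs)
}

# Trapezoidal integral of y[i0:i1] on a uniform grid at rate fs.
trapz_win <- function(y, fs, i0, i1) {
  if (i0 < 1L || i1 > length(y) || i1 <= i0) {
    stop("integration window [", i0, ", ", i1, "] outside series of length ",
         length(y), call. = FALSE)
  }
  pracma::trapz(seq(i0, i1) / fs, y[i0:i1])
}

clip01 <- function(x) {
  # dimension-preserving (pmax(0, x) would take attributes from the scalar)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
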