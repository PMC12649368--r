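#' Linear envelope of a raw surface EMG channel
#'
#' Standard linear-envelope chain: zero-phase second-order Butterworth
#' band-pass (30-450 Hz), full-wave rectification, zero-phase second-order
#' Butterworth low-pass (6 Hz). Small negative excursions produced by the
#' final filter are clipped to zero.
#'
#' @param x Raw EMG samples (V).
#' @param fs Sampling rate (Hz); must be at least 1000 Hz so that the 450 Hz
#'   band edge is below Nyquist.
#' @param band Band-pass edges (Hz).
#' @param lowpass Envelope low-pass cutoff (Hz).
#' @return Numeric envelope, same length as `x`, nonnegative. The attribute
#'   `"fs"` carries the sampling rate.
#' @export
emg_envelope <- function(x, fs, band = c(30, 450), lowpass = 6) {
  if (fs < 2 * band[2]) {
    stop("sampling rate ", fs, " Hz violates Nyquist for the ", band[2],
         " Hz band edge")
  }
  if (fs < 1000) stop("EMG sampling rate must be >= 1000 Hz")
  if (length(x) <= 24) stop("EMG series too short to filter (length ", length(x), ")")
  if (any(!is.finite(x))) stop("EMG series contains non-finite samples")
  env <- bandpass_zp(x, fs, band[1], band[2], order = 2)
  env <- lowpass_zp(abs(env), fs, lowpass, order = 2)
  env <- pmax(env, 0)
  attr(env, "fs") <- fs
  env
}

#' Normalize an EMG envelope to a task peak
#'
#' Divides the envelope by the channel's peak envelope value over the
#' subject's task cycles and clips the result into `[0, 1]`, yielding the
#' neural excitation that drives the activation dynamics.
#'
#' @param env Envelope values (from [emg_envelope()]).
#' @param task_peak Per-channel maximum envelope over the subject's task
#'   cycles; must be positive.
#' @return Excitation series in `[0, 1]`.
#' @export
normalize_excitation <- function(env, task_peak) {
  if (!is.finite(task_peak) || task_peak <= 0) {
    stop("task_peak must be a positive number")
  }
  clip01(as.numeric(env) / task_peak)
}

# Double real pole of the activation recursion whose cascade has its -3 dB
# point at `fc` Hz when run at `fs` Hz. Returns gamma (negative; pole = -gamma).
activation_gamma <- function(fs, fc = 2) {
  w <- 2 * pi * fc / fs
  # |1 - p e^{-iw}|^2 = sqrt(2) (1 - p)^2, p in (0, 1)
  a <- 1 - sqrt(2)
  b <- 2 * sqrt(2) - 2 * cos(w)
  disc <- b^2 - 4 * a^2
  p <- (-b + sqrt(disc)) / (2 * a)
  if (!(p > 0 && p < 1)) p <- (-b - sqrt(disc)) / (2 * a)
  -p
}

# Exponential shaping nonlinearity a = (exp(A u) - 1) / (exp(A) - 1).
shape_nonlinearity <- function(u, A) {
  if (!is.finite(A) || A >= 0 || A < -3) {
    stop("activation shape A must lie in [-3, 0)")
  }
  clip01((exp(A * u) - 1) / (exp(A) - 1))
}

#' Activation dynamics: excitation to muscle activation
#'
#' Converts normalized excitation e(t) into muscle activation a(t) in `[0,1]`
#' with the canonical discrete two-pole recursion followed by an exponential
#' shaping nonlinearity:
#' \deqn{u(t) = \alpha e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2)}
#' with unit DC gain (\eqn{\alpha - \beta_1 - \beta_2 = 1}) and the double
#' pole placed so the recursion's -3 dB point sits at `fc` (default 2 Hz) at
#' the working rate, then
#' \deqn{a = (e^{A u} - 1) / (e^{A} - 1), \quad A \in [-3, 0).}
#'
#' @param e Excitation in `[0, 1]`.
#' @param fs Sampling rate (Hz).
#' @param A Nonlinearity shape in `[-3, 0)`; values near 0 approach linearity.
#' @param delay Electromechanical delay d (s).
#' @param fc Recursion cutoff (Hz).
#' @return List with `a` (activation in `[0,1]`), `u` (linear-stage output,
#'   kept for calibration), and `fs`.
#' @export
activation_dynamics <- function(e, fs, A = -1.5, delay = 0.04, fc = 2) {
  e <- as.numeric(e)
  if (any(!is.finite(e)) || any(e < -1e-9) || any(e > 1 + 1e-9)) {
    stop("excitation must lie in [0, 1]")
  }
  e <- clip01(e)
  g <- activation_gamma(fs, fc)
  if (abs(g) >= 1) stop("unstable recursion coefficients (|gamma| >= 1)")
  beta1 <- 2 * g
  beta2 <- g^2
  alpha <- 1 + beta1 + beta2
  d <- round(delay * fs)
  e_del <- if (d > 0) c(rep(e[1], d), e[seq_len(length(e) - d)]) else e
  u <- as.numeric(stats::filter(alpha * e_del, c(-beta1, -beta2),
                                method = "recursive"))
  u <- clip01(u)
  list(a = shape_nonlinearity(u, A), u = u, fs = fs)
}
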