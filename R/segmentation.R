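#' Segmentation configuration
#'
#' @param onset_frac Movement-onset threshold as a fraction of trial peak
#'   speed.
#' @param rest_frac Dynamic rest threshold as a fraction of trial peak speed,
#'   used for movement termination and for refining touch events to the
#'   centre of their zero-velocity dwell.
#' @param lowpass_hz Zero-phase low-pass cutoff (Hz) applied to positions and
#'   speed before landmark search, suppressing tremor-induced spurious
#'   extrema.
#' @param polarity `"auto"` infers the sagittal (x) polarity of the reach from
#'   the first large displacement; `"max"`/`"min"` force the target-touch
#'   extremum type.
#' @return List of class `segment_config`.
#' @export
segment_config <- function(onset_frac = 0.05, rest_frac = 0.02,
                           lowpass_hz = 6, polarity = c("auto", "max", "min")) {
  polarity <- match.arg(polarity)
  stopifnot(onset_frac > 0, onset_frac < 1, rest_frac > 0, rest_frac < 1,
            lowpass_hz > 0)
  structure(list(onset_frac = onset_frac, rest_frac = rest_frac,
                 lowpass_hz = lowpass_hz, polarity = polarity),
            class = "segment_config")
}

seg_fail <- function(landmark) {
  stop("phase segmentation failed: landmark '", landmark, "' not found",
       call. = FALSE)
}

# Midpoint of the sub-threshold speed region containing (or nearest to)
# index i0, with sub-sample interpolation at both crossings. Excursions
# above threshold shorter than `gap` samples (tremor ripple) are bridged.
rest_midpoint <- function(vf, i0, thr, fs, gap = round(0.15 * fs)) {
  n <- length(vf)
  if (vf[i0] >= thr) {
    below <- which(vf < thr)
    if (!length(below)) return(NA_real_)
    i0 <- below[which.min(abs(below - i0))]
  }
  il <- i0
  repeat {
    if (il > 1L && vf[il - 1L] < thr) { il <- il - 1L; next }
    lo <- max(1L, il - gap)
    cand <- which(vf[lo:(il - 1L)] < thr)
    if (il > 1L && length(cand)) il <- lo + max(cand) - 1L else break
  }
  ir <- i0
  repeat {
    if (ir < n && vf[ir + 1L] < thr) { ir <- ir + 1L; next }
    hi <- min(n, ir + gap)
    cand <- which(vf[(ir + 1L):hi] < thr)
    if (ir < n && length(cand)) ir <- ir + min(cand) else break
  }
  tl <- if (il > 1L) {
    (il - 1L) - (thr - vf[il]) / (vf[il - 1L] - vf[il])
  } else il - 1L
  tr <- if (ir < n) {
    (ir - 1L) + (thr - vf[ir]) / (vf[ir + 1L] - vf[ir])
  } else ir - 1L
  ((tl + tr) / 2) / fs
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

#' Segment a hand-to-mouth trial into its four subphases
#'
#' Detects the five timestamps delimiting the four subphases from wrist
#' kinematics: movement onset from a preset speed threshold, the two target
#' touches from sagittal (x) position extrema, the mouth touch from the
#' vertical (z) maximum co-occurring with a speed minimum, and movement
#' termination from a dynamic 2% absolute-speed threshold. Touch events are
#' refined to the centre of their zero-velocity dwell. The procedure is fully
#' deterministic.
#'
#' @param pos `n x 3` matrix (or data frame) of wrist position (m), columns
#'   x (sagittal, forward), y (lateral), z (vertical up).
#' @param fs Sampling rate (Hz).
#' @param config A [segment_config()].
#' @return Named numeric vector `c(b0, b1, b2, b3, b4)` (s), strictly
#'   increasing, of class `phase_boundaries`.
#' @export
segment_phases <- function(pos, fs, config = segment_config()) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop("wrist position must have 3 columns (x, y, z)")
  n <- nrow(pos)
  if (n < 10L * fs / 100) stop("position series too short to segment")
  if (stats::sd(pos[, 1]) < 1e-9 && stats::sd(pos[, 3]) < 1e-9) {
    seg_fail("movement (flat position signal)")
  }
  pf <- apply(pos, 2, lowpass_zp, fs = fs, fc = config$lowpass_hz)
  xf <- pf[, 1]
  zf <- pf[, 3]
  # differentiate the filtered positions: the norm of raw-noise derivatives
  # would otherwise leave a rectified noise floor above the rest threshold
  vf <- sqrt(rowSums(apply(pf, 2, deriv_c, fs = fs)^2))
  vmax <- max(vf)
  if (vmax < 1e-9) seg_fail("movement (zero velocity)")
  thr_on <- config$onset_frac * vmax
  thr_rest <- config$rest_frac * vmax

  # movement onset: first upward crossing that is sustained (noise spikes
  # near the rest floor do not persist)
  hold <- round(0.15 * fs)
  ion <- which(vf >= thr_on)
  ion <- ion[vapply(ion, function(i) {
    hi <- min(n, i + hold)
    mean(vf[i:hi] >= thr_on) > 0.9
  }, TRUE)]
  if (!length(ion)) seg_fail("onset")
  i_b0 <- ion[1L]
  b0 <- if (i_b0 > 1L) {
    ((i_b0 - 1L) - (vf[i_b0] - thr_on) / (vf[i_b0] - vf[i_b0 - 1L])) / fs
  } else 0

  s <- switch(config$polarity,
              auto = {
                # reach polarity from the first major sagittal excursion
                # (the later mouth transport can displace x further the
                # other way)
                dx <- xf - xf[1]
                i_first <- which(abs(dx) >= 0.5 * max(abs(dx)))[1]
                sign(dx[i_first])
              },
              max = 1, min = -1)
  if (s == 0) seg_fail("reach direction")
  sx <- s * xf

  i_z <- i_b0 - 1L + which.max(zf[i_b0:n])
  if (vf[i_z] >= thr_on) seg_fail("mouth touch (no speed minimum at z peak)")
  b2 <- rest_midpoint(vf, i_z, thr_rest, fs)
  if (is.na(b2)) seg_fail("mouth touch")

  pick_touch <- function(from, to, landmark) {
    cand <- local_maxima(sx[from:to]) + from - 1L
    cand <- cand[vf[cand] < thr_on]
    if (!length(cand)) seg_fail(landmark)
    i <- cand[which.max(sx[cand])]
    bt <- rest_midpoint(vf, i, thr_rest, fs)
    if (is.na(bt)) seg_fail(landmark)
    bt
  }
  i_b2 <- round(b2 * fs) + 1L
  b1 <- pick_touch(i_b0, i_b2, "first target touch")
  b3 <- pick_touch(i_b2, n, "second target touch")

  # movement termination: last downward crossing of the dynamic threshold
  # that is followed by sustained rest (isolated noise spikes in the final
  # rest would otherwise postpone it)
  i_b3 <- min(round(b3 * fs) + 1L, n)
  hold_end <- round(0.25 * fs)
  cross <- i_b3 - 1L +
    which(vf[i_b3:(n - 1L)] >= thr_rest & vf[(i_b3 + 1L):n] < thr_rest)
  cross <- cross[vapply(cross, function(i) {
    hi <- min(n, i + hold_end)
    mean(vf[(i + 1L):hi] < thr_rest) > 0.9
  }, TRUE)]
  if (!length(cross)) seg_fail("movement termination")
  i_end <- cross[1L]
  b4 <- ((i_end - 1L) + (vf[i_end] - thr_rest) / (vf[i_end] - vf[i_end + 1L])) / fs

  b <- c(b0 = b0, b1 = b1, b2 = b2, b3 = b3, b4 = b4)
  if (any(diff(b) <= 0) || b[1] < 0 || b[5] > (n - 1L) / fs) {
    seg_fail("boundary ordering")
  }
  structure(b, class = "phase_boundaries")
}

#' Apply manual boundary corrections
#'
#' Overrides automatically detected boundaries with rows from a sidecar table
#' (columns `trial`, `b0`..`b4`), mirroring a visual-inspection correction
#' step.
#'
#' @param boundaries Named list of `phase_boundaries` keyed by trial id.
#' @param overrides Data frame with columns `trial`, `b0`..`b4` (s).
#' @return The corrected list.
#' @export
apply_boundary_overrides <- function(boundaries, overrides) {
  stopifnot(all(c("trial", "b0", "b1", "b2", "b3", "b4") %in% names(overrides)))
  for (i in seq_len(nrow(overrides))) {
    id <- as.character(overrides$trial[i])
    b <- as.numeric(overrides[i, c("b0", "b1", "b2", "b3", "b4")])
    if (any(diff(b) <= 0)) stop("override for trial ", id, " is not increasing")
    boundaries[[id]] <- structure(stats::setNames(b, c("b0", "b1", "b2", "b3", "b4")),
                                  class = "phase_boundaries")
  }
  boundaries
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1) from the standard mean-squares decomposition of an n-targets by
#' k-raters matrix.
#'
#' @param Y Numeric matrix, rows = targets, columns = raters/runs.
#' @return ICC value, or `NA` (with a message) when the between-target
#'   variance is zero and the coefficient is undefined.
#' @export
icc_agreement <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(Y)
  rm_ <- rowMeans(Y); cm_ <- colMeans(Y)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-15 || msr < 1e-15) {
    message("ICC undefined: zero between-target variance")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Evaluate segmentation accuracy against a reference
#'
#' Pools the five transition-timestamp errors over all trials and reports the
#' mean absolute error, root-mean-square error (both ms), per-boundary MAE,
#' and the absolute-agreement ICC between predicted and reference timings.
#'
#' @param predicted,reference Lists (same length) of `phase_boundaries`.
#' @return List of class `segmentation_evaluation` with `mae`, `rmse`, `icc`,
#'   `per_boundary` (named, ms).
#' @export
evaluate_segmentation <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference trial lists differ in length")
  }
  P <- do.call(rbind, lapply(predicted, as.numeric))
  R <- do.call(rbind, lapply(reference, as.numeric))
  err <- (P - R) * 1000
  res <- list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
              icc = icc_agreement(cbind(as.vector(P), as.vector(R))),
              per_boundary = stats::setNames(colMeans(abs(err)),
                                             c("b0", "b1", "b2", "b3", "b4")))
  class(res) <- "segmentation_evaluation"
  res
}

#' Test-retest repeatability of segmentation
#'
#' ICC(2,1) for absolute agreement between two executions of the segmentation
#' on the same trials, on pooled boundary times.
#'
#' @param run_a,run_b Lists of `phase_boundaries` from the two runs.
#' @return ICC value (1 for a deterministic algorithm), or `NA` if undefined.
#' @export
repeatability <- function(run_a, run_b) {
  if (length(run_a) != length(run_b)) stop("runs differ in length")
  A <- unlist(lapply(run_a, as.numeric))
  B <- unlist(lapply(run_b, as.numeric))
  icc_agreement(cbind(A, B))
}
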