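#' SPARC parameters
#'
#' @param amp_threshold Amplitude threshold (fraction of the zero-frequency
#'   magnitude) used for the adaptive cutoff selection.
#' @param max_cutoff_hz Upper bound (Hz) on the adaptive cutoff.
#' @param pad_factor Zero-padding factor (>= 1) for the spectrum.
#' @return List of class `sparc_params`.
#' @export
sparc_params <- function(amp_threshold = 0.05, max_cutoff_hz = 10,
                         pad_factor = 4) {
  stopifnot(amp_threshold > 0, amp_threshold < 1, max_cutoff_hz > 0,
            pad_factor >= 1)
  structure(list(amp_threshold = amp_threshold,
                 max_cutoff_hz = max_cutoff_hz,
                 pad_factor = pad_factor),
            class = "sparc_params")
}

#' Spectral arc length (SPARC) smoothness of a torque window
#'
#' Negative arc length of the normalized magnitude spectrum of the signal,
#' traversed from zero frequency up to an adaptively selected cutoff: the
#' highest frequency (below `max_cutoff_hz`) at which the spectrum, normalized
#' by its zero-frequency value, still reaches `amp_threshold`. Values are
#' negative; closer to zero means smoother. The metric is invariant to
#' amplitude scaling.
#'
#' @param x Signal window (torque), at least 0.25 s long.
#' @param fs Sampling rate (Hz).
#' @param params A [sparc_params()].
#' @return Negative scalar smoothness.
#' @export
sparc <- function(x, fs, params = sparc_params()) {
  x <- as.numeric(x)
  if (length(x) < ceiling(0.25 * fs)) {
    stop("SPARC window shorter than 0.25 s")
  }
  if (all(x == 0)) stop("smoothness undefined for an all-zero window")
  nfft <- 2^ceiling(log2(length(x) * params$pad_factor))
  V <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))[seq_len(nfft / 2 + 1)]
  f <- (seq_len(nfft / 2 + 1) - 1) * fs / nfft
  if (V[1] <= 1e-12 * max(V)) {
    stop("smoothness undefined: zero-frequency magnitude vanishes")
  }
  Vh <- V / V[1]
  in_band <- which(f <= params$max_cutoff_hz & Vh >= params$amp_threshold)
  i_c <- max(in_band)
  if (i_c < length(f) && f[i_c + 1] <= params$max_cutoff_hz) {
    # sub-bin interpolation of the threshold crossing
    fc <- f[i_c] + (f[i_c + 1] - f[i_c]) *
      (Vh[i_c] - params$amp_threshold) / (Vh[i_c] - Vh[i_c + 1])
    fc <- min(fc, params$max_cutoff_hz)
  } else {
    fc <- params$max_cutoff_hz
  }
  keep <- which(f < fc)
  Vc <- stats::approx(f, Vh, xout = fc)$y
  fg <- c(f[keep], fc)
  Vg <- c(Vh[keep], Vc)
  -sum(sqrt((diff(fg) / fc)^2 + diff(Vg)^2))
}

#' Phase-windowed mechanical work
#'
#' Trapezoidal integral of instantaneous power (force times contraction
#' velocity for a muscle, torque times angular velocity for a joint) over a
#' window, normalized by body mass. Sign is preserved: positive work is
#' concentric, negative eccentric.
#'
#' @param force Force (N) or torque (N m) series.
#' @param velocity Aligned contraction velocity (m/s) or angular velocity
#'   (rad/s) series.
#' @param fs Sampling rate (Hz).
#' @param window Integer sample indices `c(i0, i1)` of the phase.
#' @param mass Body mass (kg), positive.
#' @return Work (J/kg).
#' @export
mechanical_work <- function(force, velocity, fs, window, mass) {
  stopifnot(length(force) == length(velocity), mass > 0)
  trapz_win(as.numeric(force) * as.numeric(velocity), fs,
            window[1], window[2]) / mass
}

#' Torque-based co-contraction index (TCCI)
#'
#' Each torque is rectified and normalized by that muscle's maximum absolute
#' torque over the whole task; the index is the time-average of the pointwise
#' minimum of the two normalized profiles over the window:
#' \deqn{TCCI = \frac{1}{\Delta t}\int \min(\hat\tau_{ag}, \hat\tau_{ant}) dt}
#' TCCI lies in `[0, 1]`: 0 means no overlap, 1 sustained simultaneous
#' maximal torque.
#'
#' @param tau_ag,tau_ant Aligned agonist and antagonist muscle torque series
#'   (N m).
#' @param fs Sampling rate (Hz).
#' @param window Integer sample indices `c(i0, i1)`.
#' @param max_ag,max_ant Whole-task maxima of the absolute torques; default
#'   computed from the full series. Must be positive.
#' @return TCCI in `[0, 1]`.
#' @export
tcci <- function(tau_ag, tau_ant, fs, window,
                 max_ag = max(abs(tau_ag)), max_ant = max(abs(tau_ant))) {
  stopifnot(length(tau_ag) == length(tau_ant))
  if (!is.finite(max_ag) || max_ag <= 0 || !is.finite(max_ant) || max_ant <= 0) {
    stop("co-contraction index undefined: zero task-maximum torque")
  }
  m <- pmin(abs(tau_ag) / max_ag, abs(tau_ant) / max_ant)
  dt <- (window[2] - window[1]) / fs
  trapz_win(m, fs, window[1], window[2]) / dt
}

# Metric id tables -----------------------------------------------------------

htm_joints <- c("ElFE" = "el_fe", "ShFE" = "sh_fe", "ShAA" = "sh_aa",
                "ShERIR" = "sh_erir")
htm_muscle_labels <- c("BR", "BB", "TRL", "AD", "MD", "PD", "PM")
htm_tcci_pairs <- list(AD_PD = c("AD", "PD"), MD_PM = c("MD", "PM"),
                       TRL_BB = c("TRL", "BB"), TRL_BR = c("TRL", "BR"))
htm_windows <- c("PhaseI", "PhaseII", "PhaseIII", "PhaseIV", "Whole")

#' Names of the 26 biomechanical metrics
#'
#' Work and SPARC for four joint torques and seven muscle torques, plus TCCI
#' for four agonist-antagonist pairs; each evaluated over Phases I-IV and the
#' whole task (130 feature columns, named `Metric__Window`).
#'
#' @return Character vector of 26 metric ids.
#' @export
htm_metric_names <- function() {
  c(paste0("Work_", c(names(htm_joints), htm_muscle_labels)),
    paste0("Sparc_", c(names(htm_joints), htm_muscle_labels)),
    paste0("TCCI_", names(htm_tcci_pairs)))
}

# Compute the 26 x 5 metric block for one processed trial.
trial_metrics <- function(proc, boundaries, mass,
                          sparc_par = sparc_params()) {
  fs <- proc$fs_kin
  n <- nrow(proc$angles)
  bi <- pmin(pmax(round(as.numeric(boundaries) * fs) + 1L, 1L), n)
  windows <- list(PhaseI = c(bi[1], bi[2]), PhaseII = c(bi[2], bi[3]),
                  PhaseIII = c(bi[3], bi[4]), PhaseIV = c(bi[4], bi[5]),
                  Whole = c(bi[1], bi[5]))
  whole <- windows$Whole
  out <- numeric(0)
  nm <- character(0)
  for (w in names(windows)) {
    win <- windows[[w]]
    for (j in names(htm_joints)) {
      jid <- htm_joints[[j]]
      omega <- proc$ang_vel[[jid]]
      out <- c(out,
               mechanical_work(proc$joint_torque[[jid]], omega, fs, win, mass),
               sparc(proc$joint_torque[[jid]][win[1]:win[2]], fs, sparc_par))
      nm <- c(nm, paste0("Work_", j, "__", w), paste0("Sparc_", j, "__", w))
    }
    for (m in htm_muscle_labels) {
      out <- c(out,
               mechanical_work(proc$force[, m], proc$contraction_vel[, m],
                               fs, win, mass),
               sparc(proc$muscle_torque[, m][win[1]:win[2]], fs, sparc_par))
      nm <- c(nm, paste0("Work_", m, "__", w), paste0("Sparc_", m, "__", w))
    }
    for (p in names(htm_tcci_pairs)) {
      pr <- htm_tcci_pairs[[p]]
      t1 <- proc$muscle_torque[, pr[1]]
      t2 <- proc$muscle_torque[, pr[2]]
      out <- c(out, tcci(t1, t2, fs, win,
                         max_ag = max(abs(t1[whole[1]:whole[2]])),
                         max_ant = max(abs(t2[whole[1]:whole[2]]))))
      nm <- c(nm, paste0("TCCI_", p, "__", w))
    }
  }
  stats::setNames(out, nm)
}

#' Assemble the participant feature table
#'
#' Computes all 26 metrics over the four subphases and the whole task for
#' every trial, then averages the middle three trials (2-4) per participant.
#' Participants whose trials fail segmentation are excluded with a logged
#' reason.
#'
#' @param subject_results List per subject: each with `metrics` (matrix
#'   trials x 130), `group`, `severity`, `id`.
#' @return Data frame of class `feature_table`: one row per participant with
#'   `subject`, `group`, `severity` and the 130 feature columns; the
#'   `"exclusions"` attribute records dropped participants.
#' @export
extract_features <- function(subject_results) {
  rows <- list()
  excl <- character(0)
  for (res in subject_results) {
    if (!is.null(res$error)) {
      excl <- c(excl, paste0(res$id, ": ", res$error))
      next
    }
    mid <- if (nrow(res$metrics) >= 4) {
      res$metrics[2:4, , drop = FALSE]   # middle three of five trials
    } else {
      res$metrics
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = res$id, group = res$group, severity = res$severity,
      as.list(colMeans(mid)), check.names = FALSE)
  }
  if (!length(rows)) stop("no participants with valid trials")
  ft <- do.call(rbind, rows)
  attr(ft, "exclusions") <- excl
  class(ft) <- c("feature_table", class(ft))
  ft
}
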