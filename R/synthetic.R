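#' Minimum-jerk point-to-point segment
#'
#' Quintic minimum-jerk trajectory between two points: the normalized path
#' follows `10 t^3 - 15 t^4 + 6 t^5`, with zero velocity and acceleration at
#' both endpoints.
#'
#' @param p0,p1 3-vectors (m), start and end points.
#' @param T Segment duration (s), positive.
#' @param n Number of samples including both endpoints, at least 2.
#' @return `n x 3` matrix of positions.
#' @export
minimum_jerk_segment <- function(p0, p1, T, n) {
  if (any(!is.finite(c(p0, p1)))) stop("endpoints must be finite")
  if (!is.finite(T) || T <= 0) stop("duration must be positive")
  if (n < 2) stop("need at least 2 samples")
  tau <- seq(0, 1, length.out = n)
  s <- mj_shape(tau)
  outer(rep(1, n), as.numeric(p0)) + outer(s, as.numeric(p1) - as.numeric(p0))
}

mj_shape <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_speed <- function(tau) 30 * tau^2 * (1 - tau)^2   # d(shape)/d(tau)

#' Hand-to-mouth task geometry
#'
#' Waypoints of the standardized drinking-like task in shoulder-centred
#' coordinates (x forward, y lateral, z vertical up, metres): a start position
#' with the arm down and the elbow at 90 degrees (hand flat on the table), a
#' target on the table calibrated to a fraction of arm length, and a mouth
#' position near the face. `lift_scale < 1` lowers the effective mouth height,
#' emulating the head-to-hand compensation of impaired reachers.
#'
#' @param upper_arm,forearm Segment lengths (m).
#' @param target_frac Target forward distance as a fraction of arm length.
#' @param mouth_x,mouth_z Nominal mouth position (m, shoulder-centred).
#' @param lift_scale Fraction in (0, 1] of the nominal table-to-mouth rise.
#' @param phase_durations Durations (s) of the four movement phases.
#' @param dwell Zero-velocity dwell (s) at the target and mouth touches.
#' @return An object of class `task_geometry`.
#' @export
task_geometry <- function(upper_arm = 0.31, forearm = 0.34,
                          target_frac = 0.8, mouth_x = 0.12, mouth_z = 0.12,
                          lift_scale = 1,
                          phase_durations = c(1.0, 1.2, 1.2, 1.0),
                          dwell = 0.1) {
  arm_length <- upper_arm + forearm
  start <- c(forearm, 0, -upper_arm)
  target <- c(target_frac * arm_length, 0, -upper_arm)
  # head-to-hand compensation: an incomplete lift comes with the head leaning
  # toward the hand, which moves the effective mouth position forward and
  # reduces the elbow flexion excursion
  mouth <- c(mouth_x + 0.5 * (1 - lift_scale), 0,
             start[3] + lift_scale * (mouth_z - start[3]))
  if (target[1] - start[1] <= 0) stop("target must lie forward of the start")
  if (mouth[3] <= target[3]) stop("mouth must lie above the target")
  if (any(!is.finite(phase_durations)) || any(phase_durations <= 0)) {
    stop("phase durations must be positive")
  }
  structure(list(start_pos = start, target_pos = target, mouth_pos = mouth,
                 phase_durations = phase_durations, dwell = dwell,
                 upper_arm = upper_arm, forearm = forearm),
            class = "task_geometry")
}

#' Impairment profile
#'
#' Per-subject generative parameters of the synthetic cohort. The healthy
#' profile is `(force_scale = 1, baseline coactivation, no tremor,
#' duration_scale = 1)`.
#'
#' @param force_scale Fraction in (0, 1] of preserved output capacity.
#' @param coactivation_level Antagonist co-drive as a fraction in `[0, 1)` of
#'   the agonist drive.
#' @param tremor_amplitude Velocity ripple amplitude as a fraction (>= 0) of
#'   peak movement speed.
#' @param tremor_freq Tremor frequency (Hz), typically 4-8.
#' @param duration_scale Movement slowing factor, >= 1.
#' @param severity_score Synthetic upper-extremity motor score (FMUE-like
#'   integer; higher = less impaired).
#' @return An object of class `impairment_profile`.
#' @export
impairment_profile <- function(force_scale = 1, coactivation_level = 0.05,
                               tremor_amplitude = 0, tremor_freq = 5,
                               duration_scale = 1, severity_score = NA_integer_) {
  stopifnot(force_scale > 0, force_scale <= 1,
            coactivation_level >= 0, coactivation_level < 1,
            tremor_amplitude >= 0, duration_scale >= 1)
  vals <- c(force_scale, coactivation_level, tremor_amplitude, tremor_freq,
            duration_scale)
  if (any(!is.finite(vals))) stop("profile fields must be finite")
  structure(list(force_scale = force_scale,
                 coactivation_level = coactivation_level,
                 tremor_amplitude = tremor_amplitude,
                 tremor_freq = tremor_freq,
                 duration_scale = duration_scale,
                 severity_score = severity_score),
            class = "impairment_profile")
}

#' @rdname impairment_profile
#' @export
healthy_profile <- function() impairment_profile()

# Planar two-link inverse kinematics (sagittal x-z plane, shoulder at origin).
ik_2link <- function(x, z, l1, l2) {
  d2 <- x^2 + z^2
  d <- sqrt(d2)
  if (any(d > (l1 + l2) * 0.9995) || any(d < abs(l1 - l2) * 1.0005)) {
    stop("wrist path unreachable for limb lengths (", l1, ", ", l2, ")")
  }
  cq2 <- (d2 - l1^2 - l2^2) / (2 * l1 * l2)
  q2 <- acos(pmin(pmax(cq2, -1), 1))
  phi <- atan2(x, -z)
  psi <- atan2(l2 * sin(q2), l1 + l2 * cos(q2))
  list(sh_fe = phi - psi, el_fe = q2)
}

# Band-limited (2 Hz) random drift with a prescribed standard deviation.
drift_noise <- function(n, fs, sd_target, fc = 2) {
  w <- lowpass_zp(stats::rnorm(n), fs, fc)
  s <- stats::sd(w)
  if (s < .Machine$double.eps) return(rep(0, n))
  w * (sd_target / s)
}

#' Generate one synthetic hand-to-mouth trial
#'
#' Builds the ideal wrist path as concatenated minimum-jerk segments
#' start -> target -> mouth -> target -> start (with zero-velocity dwells at
#' the touches and rest padding at both ends), derives shoulder/elbow
#' flexion-extension by planar two-link inverse kinematics plus prescribed
#' smooth abduction-adduction and rotation profiles, computes the joint torque
#' demand (two-link inverse dynamics plus single-axis models for the
#' non-sagittal angles), distributes it to agonist muscles in proportion to
#' their instantaneous torque capacity with `coactivation_level` times the
#' agonist drive added to antagonists, and synthesizes 7-channel EMG as
#' band-limited (30-450 Hz) noise amplitude-modulated by the neural drive.
#' Action tremor is injected as a velocity ripple at `tremor_freq`
#' proportional to the instantaneous ideal speed. Kinematics are sampled at
#' 400 Hz, EMG at 2000 Hz; measured channels carry band-limited drift plus
#' white measurement noise.
#'
#' @param geometry A [task_geometry()].
#' @param profile An [impairment_profile()].
#' @param muscles Muscle set, as [default_muscle_set()].
#' @param seed Integer seed; regeneration from the same arguments is
#'   bit-identical.
#' @param arm An [arm_model()]; limb lengths should match the geometry.
#' @param fs_kin,fs_emg Sampling rates (Hz).
#' @param pad Rest padding (s) before and after the movement.
#' @param onset_frac,rest_frac Speed-threshold conventions (fractions of peak
#'   speed) defining the recorded movement onset and termination truths.
#' @param noise List of measurement-noise magnitudes: `pos_drift`, `pos_white`
#'   (m), `ang_drift`, `ang_white` (rad).
#' @param keep_internals If `TRUE`, the returned object additionally carries
#'   `truth_activation` (400 Hz matrix), `truth_angles` and `truth_support`
#'   for validation studies.
#' @return An object of class `htm_synthetic_trial`: list with `trial` (the
#'   raw-signal record), `truth_boundaries` (named b0..b4, s),
#'   `truth_profile`, and `seed`.
#' @export
generate_trial <- function(geometry, profile, muscles = default_muscle_set(),
                           seed = 1L, arm = NULL,
                           fs_kin = 400, fs_emg = 2000, pad = 0.5,
                           onset_frac = 0.05, rest_frac = 0.02,
                           noise = list(pos_drift = 2e-4, pos_white = 3e-5,
                                        ang_drift = 2e-3, ang_white = 1e-4),
                           keep_internals = FALSE) {
  stopifnot(inherits(geometry, "task_geometry"),
            inherits(profile, "impairment_profile"))
  if (is.null(arm)) {
    arm <- arm_model(upper_arm = geometry$upper_arm, forearm = geometry$forearm)
  }
  with_seed(seed, {
    l1 <- geometry$upper_arm; l2 <- geometry$forearm
    way <- list(geometry$start_pos, geometry$target_pos, geometry$mouth_pos,
                geometry$target_pos, geometry$start_pos)
    Tm <- geometry$phase_durations * profile$duration_scale
    dw <- geometry$dwell
    segs <- list(
      list(kind = "rest", T = pad, p = way[[1]]),
      list(kind = "move", T = Tm[1], p0 = way[[1]], p1 = way[[2]]),
      list(kind = "rest", T = dw, p = way[[2]]),
      list(kind = "move", T = Tm[2], p0 = way[[2]], p1 = way[[3]]),
      list(kind = "rest", T = dw, p = way[[3]]),
      list(kind = "move", T = Tm[3], p0 = way[[3]], p1 = way[[4]]),
      list(kind = "rest", T = dw, p = way[[4]]),
      list(kind = "move", T = Tm[4], p0 = way[[4]], p1 = way[[5]]),
      list(kind = "rest", T = pad, p = way[[5]])
    )
    nseg <- vapply(segs, function(s) max(1L, as.integer(round(s$T * fs_kin))), 1L)
    starts <- cumsum(c(1L, nseg[-length(nseg)]))
    n <- sum(nseg)
    t_kin <- (seq_len(n) - 1L) / fs_kin

    pos <- matrix(0, n, 3)
    for (i in seq_along(segs)) {
      idx <- starts[i]:(starts[i] + nseg[i] - 1L)
      if (segs[[i]]$kind == "rest") {
        pos[idx, ] <- matrix(segs[[i]]$p, length(idx), 3, byrow = TRUE)
      } else {
        tau <- (seq_along(idx) - 1L) / nseg[i]
        pos[idx, ] <- outer(rep(1, length(idx)), segs[[i]]$p0) +
          outer(mj_shape(tau), segs[[i]]$p1 - segs[[i]]$p0)
      }
    }

    # --- ground-truth boundaries ---------------------------------------
    move_ix <- which(vapply(segs, function(s) s$kind == "move", TRUE))
    D <- vapply(segs[move_ix], function(s) sqrt(sum((s$p1 - s$p0)^2)), 1)
    Tmove <- vapply(segs[move_ix], function(s) s$T, 1)
    vmax <- max(1.875 * D / Tmove)
    tau_cross <- function(frac, Ti, Di) {
      k <- sqrt(frac * vmax * Ti / (30 * Di))
      if (4 * k >= 1) stop("speed threshold never crossed in segment")
      (1 - sqrt(1 - 4 * k)) / 2
    }
    t_seg_start <- (starts - 1L) / fs_kin
    b0 <- t_seg_start[move_ix[1]] + tau_cross(onset_frac, Tmove[1], D[1]) * Tmove[1]
    dwell_mid <- function(i) t_seg_start[i] + nseg[i] / (2 * fs_kin)
    b1 <- dwell_mid(3L); b2 <- dwell_mid(5L); b3 <- dwell_mid(7L)
    b4 <- t_seg_start[move_ix[4]] +
      (1 - tau_cross(rest_frac, Tmove[4], D[4])) * Tmove[4]
    truth <- c(b0 = b0, b1 = b1, b2 = b2, b3 = b3, b4 = b4)

    # --- action tremor: velocity ripple scaled by instantaneous speed ---
    v_ideal <- apply(pos, 2, deriv_c, fs = fs_kin)
    speed_ideal <- sqrt(rowSums(v_ideal^2))
    if (profile$tremor_amplitude > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- profile$tremor_amplitude * speed_ideal /
        (2 * pi * profile$tremor_freq)
      dir <- v_ideal / pmax(speed_ideal, 1e-9)
      ripple <- amp * sin(2 * pi * profile$tremor_freq * t_kin + ph)
      pos_true <- pos + dir * ripple
    } else {
      pos_true <- pos
    }

    # --- joint angles --------------------------------------------------
    qs <- ik_2link(pos_true[, 1], pos_true[, 3], l1, l2)
    blend <- function(rise_seg, fall_seg) {
      b <- numeric(n)
      ir <- starts[rise_seg]:(starts[rise_seg] + nseg[rise_seg] - 1L)
      b[ir] <- mj_shape((seq_along(ir) - 1L) / nseg[rise_seg])
      if (fall_seg > rise_seg + 1L) {
        b[(starts[rise_seg] + nseg[rise_seg]):(starts[fall_seg] - 1L)] <- 1
      }
      ifl <- starts[fall_seg]:(starts[fall_seg] + nseg[fall_seg] - 1L)
      b[ifl] <- 1 - mj_shape((seq_along(ifl) - 1L) / nseg[fall_seg])
      b
    }
    ang_ripple <- function(scale) {
      if (profile$tremor_amplitude == 0) return(0)
      ph <- stats::runif(1, 0, 2 * pi)
      profile$tremor_amplitude * scale * (speed_ideal / max(speed_ideal)) *
        sin(2 * pi * profile$tremor_freq * t_kin + ph)
    }
    # small angular ripple: at tremor frequencies even fractions of a degree
    # produce inertial torque ripple comparable to the static demand.
    # The arm stays slightly abducted throughout the movement (sustained
    # medial-deltoid demand) with an extra abduction bump during transport.
    sh_aa <- 0.12 * blend(2L, 8L) + 0.10 * blend(4L, 6L) + ang_ripple(0.001)
    sh_erir <- -0.20 * blend(2L, 8L) + ang_ripple(0.001)
    angles_true <- data.frame(sh_fe = qs$sh_fe, sh_aa = sh_aa,
                              sh_erir = sh_erir, el_fe = qs$el_fe)

    # --- torque demand and activation distribution ---------------------
    idt <- inverse_dynamics_2link(angles_true$sh_fe, angles_true$el_fe,
                                  fs_kin, arm)
    # table support: while the hand rests on the table (start/end pads and
    # the target-touch dwells) the surface carries most of the arm weight,
    # so the muscular demand drops to a small residual
    support <- rep(1, n)
    for (i in c(1L, 3L, 7L, 9L)) {
      support[starts[i]:(starts[i] + nseg[i] - 1L)] <- 0.1
    }
    support <- lowpass_zp(support, fs_kin, 2)
    I_eff <- arm$I1 + arm$I2 + arm$m1 * arm$c1^2 +
      arm$m2 * (arm$upper_arm + arm$c2)^2
    G_arm <- (arm$m1 * arm$c1 + arm$m2 * (arm$upper_arm + arm$c2)) * arm$g
    demand <- list(
      sh_fe = support * idt$sh_fe,
      el_fe = support * idt$el_fe,
      sh_aa = support * (I_eff * deriv_c(deriv_c(sh_aa, fs_kin), fs_kin) +
                           G_arm * sin(sh_aa)),
      sh_erir = 0.005 * deriv_c(deriv_c(sh_erir, fs_kin), fs_kin) +
        0.2 * sh_erir
    )
    fk <- lapply(muscles, fiber_kinematics, angles = angles_true, fs = fs_kin)
    # deceleration mask: antagonists fire a braking burst over the second
    # half of each transport segment (triphasic agonist-antagonist pattern)
    decel <- numeric(n)
    for (i in move_ix) {
      half <- starts[i] + nseg[i] %/% 2L
      decel[half:(starts[i] + nseg[i] - 1L)] <- 1
    }
    decel <- clip01(lowpass_zp(decel, fs_kin, 2))
    act <- matrix(0.0, n, length(muscles),
                  dimnames = list(NULL, names(muscles)))
    for (joint in names(demand)) {
      contrib <- names(muscles)[vapply(muscles, function(m)
        joint %in% names(m$moment_arms), TRUE)]
      if (!length(contrib)) next
      r <- sapply(contrib, function(m)
        moment_arm(muscles[[m]], joint, angles_true[[joint]]))
      cap <- sapply(contrib, function(m) {
        phi <- pennation_angle(fk[[m]]$lm_norm, muscles[[m]]$phi0)
        abs(r[, m]) * muscles[[m]]$F0m * fl_active(fk[[m]]$lm_norm) *
          fv_hill(fk[[m]]$vm_norm) * cos(phi)
      })
      passive <- sapply(contrib, function(m) {
        phi <- pennation_angle(fk[[m]]$lm_norm, muscles[[m]]$phi0)
        r[, m] * muscles[[m]]$F0m * fp_passive(fk[[m]]$lm_norm,
                                               muscles[[m]]$kp) * cos(phi)
      })
      tau_active <- demand[[joint]] - rowSums(passive)
      pos_side <- r > 0
      match_side <- sweep(pos_side, 1, tau_active > 0, `==`)
      cap_sum <- rowSums(cap * match_side)
      a0 <- clip01(abs(tau_active) / pmax(cap_sum, 1e-6))
      # antagonist drive: tonic co-contraction plus a braking burst; the
      # agonists then compensate the antagonist torque so the net active
      # torque still equals the demand
      a_ant <- profile$coactivation_level * a0 + 0.5 * a0 * decel
      tau_ant <- rowSums(cap * (!match_side)) * a_ant
      a_ag <- clip01((abs(tau_active) + tau_ant) / pmax(cap_sum, 1e-6))
      for (m in contrib) {
        a_m <- ifelse(match_side[, m], a_ag, a_ant)
        act[, m] <- pmax(act[, m], a_m)
      }
    }
    act <- clip01(profile$force_scale * clip01(act + 0.01))

    # --- EMG synthesis ---------------------------------------------------
    n_emg <- 5L * n
    t_emg <- (seq_len(n_emg) - 1L) / fs_emg
    emd <- round(0.04 * fs_kin)
    emg <- matrix(0, n_emg, length(muscles),
                  dimnames = list(NULL, names(muscles)))
    bp <- signal::butter(4, c(30, 450) / (fs_emg / 2), type = "pass")
    for (m in names(muscles)) {
      # modulate by the per-channel normalized drive: the downstream
      # task-peak normalization then applies one common monotone transform
      # to every subject and channel, so group contrasts are not distorted
      # by subject-specific renormalization
      u <- act[, m] / max(act[, m])
      u_adv <- c(u[(emd + 1L):n], rep(u[n], emd))
      u_up <- stats::approx(t_kin, u_adv, xout = t_emg, rule = 2)$y
      w <- as.numeric(signal::filtfilt(bp, stats::rnorm(n_emg)))
      w <- w / stats::sd(w)
      emg[, m] <- 1e-3 * profile$force_scale * w * (u_up + 0.005)
    }

    # --- measured kinematics --------------------------------------------
    meas <- function(x, drift_sd, white_sd) {
      x + drift_noise(n, fs_kin, drift_sd) + stats::rnorm(n, 0, white_sd)
    }
    kin <- data.frame(
      time_s = t_kin,
      wrist_x = meas(pos_true[, 1], noise$pos_drift, noise$pos_white),
      wrist_y = meas(pos_true[, 2], noise$pos_drift, noise$pos_white),
      wrist_z = meas(pos_true[, 3], noise$pos_drift, noise$pos_white),
      sh_fe = meas(angles_true$sh_fe, noise$ang_drift, noise$ang_white),
      sh_aa = meas(angles_true$sh_aa, noise$ang_drift, noise$ang_white),
      sh_erir = meas(angles_true$sh_erir, noise$ang_drift, noise$ang_white),
      el_fe = meas(angles_true$el_fe, noise$ang_drift, noise$ang_white)
    )

    trial <- structure(list(emg = emg, kin = kin, fs_emg = fs_emg,
                            fs_kin = fs_kin,
                            meta = list(body_mass = arm$body_mass,
                                        arm_length = l1 + l2)),
                       class = "htm_trial")
    out <- structure(list(trial = trial, truth_boundaries = truth,
                          truth_profile = profile, seed = seed),
                     class = "htm_synthetic_trial")
    if (keep_internals) {
      out$truth_activation <- act
      out$truth_angles <- angles_true
      out$truth_support <- support
    }
    out
  })
}

#' Generate a synthetic cohort
#'
#' Samples subject-level parameters (body mass, limb lengths, impairment
#' profile with severity-linked force, coactivation, tremor and slowing) and
#' five trials per subject with trial-level jitter of target position and
#' pace. Stroke severity scores are drawn so that they correlate positively
#' with `force_scale` and negatively with `coactivation_level`, and impaired
#' subjects lower the effective mouth height in proportion to their weakness
#' (compensatory strategy).
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Integer master seed; everything downstream derives from it.
#' @param n_trials Trials per subject.
#' @param keep_trials If `FALSE`, return only the manifest (trials are
#'   regenerable from the recorded per-trial parameters and seeds).
#' @return List with `manifest` (subject and trial parameters, group labels,
#'   truth) and, if `keep_trials`, `trials`: a list per subject of
#'   `htm_synthetic_trial` objects.
#' @export
generate_cohort <- function(n_per_group = 20, seed = 1L, n_trials = 5,
                            keep_trials = TRUE) {
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  manifest <- cohort_plan(n_per_group, seed, n_trials)
  trials <- NULL
  if (keep_trials) {
    trials <- lapply(manifest$subjects, function(sub) {
      lapply(sub$trials, function(tr) materialize_trial(sub, tr))
    })
    names(trials) <- vapply(manifest$subjects, `[[`, "", "id")
  }
  list(manifest = manifest, trials = trials)
}

# Sample all cohort parameters; no signal synthesis happens here.
cohort_plan <- function(n_per_group, seed, n_trials = 5) {
  with_seed(seed, {
    base <- (as.integer(seed) %% 100000L) * 2000L
    subjects <- list()
    idx <- 0L
    for (group in c("healthy", "stroke")) {
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1L
        mass <- min(max(stats::rnorm(1, 70, 8), 50), 95)
        ua <- 0.31 * stats::runif(1, 0.95, 1.05)
        fa <- 0.34 * stats::runif(1, 0.95, 1.05)
        if (group == "healthy") {
          profile <- impairment_profile(
            force_scale = stats::runif(1, 0.97, 1),
            coactivation_level = stats::runif(1, 0.03, 0.08),
            tremor_amplitude = stats::runif(1, 0, 0.02),
            tremor_freq = stats::runif(1, 4, 7),
            duration_scale = stats::runif(1, 1, 1.05),
            severity_score = 66L)
          lift <- 1
        } else {
          sev <- as.integer(round(stats::runif(1, 21, 55)))
          shat <- (sev - 21) / 34
          profile <- impairment_profile(
            force_scale = min(max(0.5 + 0.35 * shat + stats::rnorm(1, 0, 0.04),
                                  0.35), 0.95),
            coactivation_level = min(max(0.28 - 0.18 * shat +
                                           stats::rnorm(1, 0, 0.03), 0.06), 0.45),
            tremor_amplitude = min(max(0.25 - 0.18 * shat +
                                         stats::rnorm(1, 0, 0.03), 0.03), 0.35),
            tremor_freq = stats::runif(1, 4, 7),
            duration_scale = min(max(1.6 - 0.4 * shat + stats::rnorm(1, 0, 0.05),
                                     1.05), 1.9),
            severity_score = sev)
          lift <- min(max(0.3 + 0.6 * profile$force_scale +
                            stats::rnorm(1, 0, 0.03), 0.4), 1)
        }
        trials <- lapply(seq_len(n_trials), function(k) {
          list(k = k,
               seed = base + idx * (n_trials + 1L) + k,
               dur_jitter = stats::runif(1, 0.96, 1.04),
               target_dx = stats::rnorm(1, 0, 0.008),
               mouth_dz = stats::rnorm(1, 0, 0.005))
        })
        subjects[[idx]] <- list(
          id = sprintf("%s%02d", if (group == "healthy") "H" else "S", i),
          group = group, body_mass = mass, upper_arm = ua, forearm = fa,
          arm_length = ua + fa, severity_score = profile$severity_score,
          lift_scale = lift, profile = profile, trials = trials)
      }
    }
    list(n_per_group = n_per_group, n_trials = n_trials, seed = seed,
         subjects = subjects)
  })
}

# Rebuild one trial of one subject from its recorded parameters.
materialize_trial <- function(sub, tr) {
  geom <- task_geometry(
    upper_arm = sub$upper_arm, forearm = sub$forearm,
    lift_scale = sub$lift_scale,
    mouth_z = 0.12 + tr$mouth_dz,
    target_frac = 0.8 + tr$target_dx / sub$arm_length,
    phase_durations = c(1.0, 1.2, 1.2, 1.0) * tr$dur_jitter)
  arm <- arm_model(body_mass = sub$body_mass, upper_arm = sub$upper_arm,
                   forearm = sub$forearm)
  st <- generate_trial(geom, sub$profile, seed = tr$seed, arm = arm)
  st$trial$meta$subject_id <- sub$id
  st$trial$meta$group <- sub$group
  st$trial$meta$severity <- sub$severity_score
  st
}
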