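#' Hill-type force curves
#'
#' Active force-length: Gaussian `exp(-(l - 1)^2 / 0.45)` of normalized fiber
#' length. Force-velocity: Hill hyperbola on the shortening side
#' (`fv(0) = 1`, `fv(-1) = 0`) and a saturating branch on the lengthening side
#' approaching 1.4, with matched slope at zero velocity. Passive force-length:
#' exponential toe region rising from 0 at optimal length and reaching 1 at
#' normalized length 1.7.
#'
#' @param l Normalized fiber length (fiber length / optimal length).
#' @param v Normalized fiber velocity (lengthening positive, units of
#'   10 optimal lengths per second).
#' @param kp Passive exponent.
#' @name hill_curves
NULL

#' @rdname hill_curves
#' @export
fl_active <- function(l) exp(-(l - 1)^2 / 0.45)

#' @rdname hill_curves
#' @export
fv_hill <- function(v) {
  # Hill curvature a/F0 = 0.35 (mixed-fiber arm muscles); the lengthening
  # branch constant matches the shortening-side slope at v = 0
  short <- pmax(1 + v, 0) / (1 - v / 0.35)
  leng <- (0.1037 + 1.4 * v) / (0.1037 + v)
  ifelse(v < 0, short, leng)
}

#' @rdname hill_curves
#' @export
fp_passive <- function(l, kp = 8) {
  ifelse(l > 1, expm1(kp * (l - 1)) / expm1(kp * 0.7), 0)
}

# Constant-thickness pennation: sin(phi) * l_norm = sin(phi0).
pennation_angle <- function(l, phi0) {
  asin(pmin(sin(phi0) / pmax(l, 0.1), 1))
}

#' Hill-type muscle force
#'
#' \deqn{F = F_{0m} (a \, f_l(\tilde l) \, f_v(\tilde v) + f_p(\tilde l))
#'   \cos\phi(\tilde l)}
#' with the curves of [fl_active()], [fv_hill()], [fp_passive()] and a
#' constant-thickness pennation model (\eqn{\sin\phi \cdot \tilde l =
#' \sin\phi_0}).
#'
#' @param a Activation in `[0, 1]`.
#' @param lm_norm Normalized fiber length, positive.
#' @param vm_norm Normalized fiber velocity (shortening negative).
#' @param params A [muscle_params()] object.
#' @return Muscle force (N), vectorized over the inputs.
#' @export
hill_force <- function(a, lm_norm, vm_norm, params) {
  if (any(!is.finite(lm_norm)) || any(lm_norm <= 0)) {
    stop("normalized fiber length must be positive")
  }
  if (any(!is.finite(vm_norm))) stop("fiber velocity must be finite")
  a <- clip01(a)
  phi <- pennation_angle(lm_norm, params$phi0)
  params$F0m * (a * fl_active(lm_norm) * fv_hill(vm_norm) +
                  fp_passive(lm_norm, params$kp)) * cos(phi)
}

#' Fiber kinematics from joint angles
#'
#' Rigid-tendon geometry closure. The musculotendon excursion about each
#' actuated joint is \eqn{-\int r(\theta) d\theta} from the reference posture;
#' with constant muscle thickness the fiber length is
#' \eqn{l_m = \sqrt{(l_0\cos\phi_0 + \Delta l_{mt})^2 + (l_0\sin\phi_0)^2}}.
#' Fiber velocity is obtained by central differences and normalized by
#' \eqn{10\, l_0} per second (a standard maximal shortening velocity).
#'
#' @param angles Data frame or named matrix of joint angle series (rad) with
#'   columns from `c("sh_fe", "sh_aa", "sh_erir", "el_fe")`, sampled at `fs`.
#' @param params A [muscle_params()] object.
#' @param fs Sampling rate (Hz), nominally 400.
#' @param ref_angles Named reference posture at which the fiber sits at
#'   optimal length; defaults to the task start posture (arm down, elbow at
#'   90 degrees).
#' @return List with `lm_norm`, `vm_norm` (series), `n_clamped` (samples
#'   clamped to the admissible length range (0.4, 1.7)).
#' @export
fiber_kinematics <- function(angles, params, fs,
                             ref_angles = c(sh_fe = 0, sh_aa = 0,
                                            sh_erir = 0, el_fe = pi / 2)) {
  angles <- as.data.frame(angles)
  dl <- 0
  for (joint in names(params$moment_arms)) {
    if (!joint %in% names(angles)) {
      stop("angle series lacks joint '", joint, "' actuated by ", params$name)
    }
    th <- angles[[joint]]
    dl <- dl - (moment_arm_integral(params, joint, th) -
                  moment_arm_integral(params, joint, ref_angles[[joint]]))
  }
  proj <- params$l0 * cos(params$phi0) + dl
  h <- params$l0 * sin(params$phi0)
  lm <- sqrt(pmax(proj, 0)^2 + h^2)
  lm_norm <- lm / params$l0
  clamped <- lm_norm <= 0.4 | lm_norm >= 1.7
  lm_norm <- pmin(pmax(lm_norm, 0.4), 1.7)
  vm <- deriv_c(lm_norm * params$l0, fs)
  list(lm_norm = lm_norm, vm_norm = vm / (10 * params$l0),
       n_clamped = sum(clamped))
}

#' Muscle torque at a joint
#'
#' \eqn{\tau_m(t) = r_m(\theta(t)) F_m(t)} with the signed moment arm, so
#' flexion/abduction-positive torques follow the moment-arm convention.
#'
#' @param force Muscle force series (N).
#' @param angles Joint angle series (rad) for the joint of interest, aligned
#'   with `force`.
#' @param params A [muscle_params()] object.
#' @param joint Joint id; defaults to the muscle's primary joint.
#' @return Torque series (N m).
#' @export
muscle_torque <- function(force, angles, params, joint = NULL) {
  joint <- joint %||% params$primary_joint
  r <- moment_arm(params, joint, as.numeric(angles))
  r * as.numeric(force)
}

#' Net joint torque
#'
#' Pointwise sum of the muscle torque series contributing at one joint.
#'
#' @param torques List (or matrix columns) of aligned muscle torque series.
#' @return Numeric net torque series.
#' @export
net_joint_torque <- function(torques) {
  if (is.matrix(torques)) torques <- asplit(torques, 2)
  if (length(torques) == 0) stop("no contributing muscles for this joint")
  n <- unique(vapply(torques, length, 1L))
  if (length(n) != 1L) stop("muscle torque series are not aligned")
  Reduce(`+`, lapply(torques, as.numeric))
}

#' Inverse dynamics of a planar two-link arm
#'
#' Lagrangian equations of a double pendulum in the sagittal plane with
#' gravity, parameterized by the shoulder flexion angle (from the downward
#' vertical) and elbow flexion (relative). Angular velocities and
#' accelerations are obtained by central differences.
#'
#' @param sh_fe Shoulder flexion-extension angle series (rad).
#' @param el_fe Elbow flexion angle series (rad).
#' @param fs Sampling rate (Hz).
#' @param arm An [arm_model()] object.
#' @return Data frame with columns `sh_fe`, `el_fe`: net joint torques (N m).
#' @export
inverse_dynamics_2link <- function(sh_fe, el_fe, fs, arm = arm_model()) {
  q1 <- as.numeric(sh_fe); q2 <- as.numeric(el_fe)
  if (length(q1) != length(q2)) stop("angle series lengths differ")
  if (length(q1) < 5) stop("angle series shorter than 5 samples")
  q1d <- deriv_c(q1, fs); q2d <- deriv_c(q2, fs)
  q1dd <- deriv_c(q1d, fs); q2dd <- deriv_c(q2d, fs)
  m1 <- arm$m1; m2 <- arm$m2; l1 <- arm$upper_arm
  c1 <- arm$c1; c2 <- arm$c2; I1 <- arm$I1; I2 <- arm$I2; g <- arm$g
  M11 <- I1 + I2 + m1 * c1^2 + m2 * (l1^2 + c2^2 + 2 * l1 * c2 * cos(q2))
  M12 <- I2 + m2 * (c2^2 + l1 * c2 * cos(q2))
  M22 <- I2 + m2 * c2^2
  h <- m2 * l1 * c2 * sin(q2)
  G1 <- (m1 * c1 + m2 * l1) * g * sin(q1) + m2 * c2 * g * sin(q1 + q2)
  G2 <- m2 * c2 * g * sin(q1 + q2)
  tau1 <- M11 * q1dd + M12 * q2dd - h * q2d * (2 * q1d + q2d) + G1
  tau2 <- M12 * q1dd + M22 * q2dd + h * q1d^2 + G2
  data.frame(sh_fe = tau1, el_fe = tau2)
}

#' Downsample activations to the kinematic rate
#'
#' Decimation by an integer factor (default 2000 Hz -> 400 Hz). The activation
#' dynamics already band-limit the signal to ~2 Hz, so plain decimation is
#' alias-free.
#'
#' @param a Activation series at the EMG rate.
#' @param factor Integer decimation factor.
#' @return Activation series at the kinematic rate.
#' @export
align_rates <- function(a, factor = 5L) {
  a <- as.numeric(a)
  if (length(a) %% factor != 0L) {
    stop("series length ", length(a), " is not a multiple of the decimation ",
         "factor ", factor, "; timebases are misaligned")
  }
  a[seq(1L, length(a), by = factor)]
}

#' Calibrate maximal isometric force scales and activation shape
#'
#' Bounded minimization of the RMSE between the model net joint torques
#' (shoulder and elbow flexion-extension) and the inverse-dynamics reference
#' torques, over per-muscle scale factors on F0m (within +/-50%) and a shared
#' activation-shape parameter A in `[-3, -0.01]`. Tendon properties and
#' optimal fiber lengths are held fixed (rigid-tendon simplification).
#'
#' @param u Matrix of linear-stage neural drive at 400 Hz, one column per
#'   muscle (the pre-nonlinearity output of [activation_dynamics()]).
#' @param angles Joint angle data frame at 400 Hz.
#' @param id_torques Data frame from [inverse_dynamics_2link()].
#' @param muscles Muscle set, as [default_muscle_set()].
#' @param arm An [arm_model()] (unused directly; kept for interface symmetry).
#' @param idx Optional sample indices over which the torque error is
#'   evaluated (e.g. a movement phase); default all samples.
#' @param maxit Maximum optimizer iterations.
#' @return List with `scales` (named), `A`, `rmse` (N m), `convergence`.
#' @export
calibrate_muscles <- function(u, angles, id_torques, muscles,
                              arm = arm_model(), idx = NULL, maxit = 200) {
  mnames <- names(muscles)
  stopifnot(all(colnames(u) == mnames))
  if (is.null(idx)) idx <- seq_len(nrow(angles))
  fk <- lapply(muscles, fiber_kinematics, angles = angles, fs = 400)
  model_torque <- function(scales, A) {
    tau <- list(sh_fe = 0, el_fe = 0)
    for (m in mnames) {
      a <- shape_nonlinearity(u[, m], A)
      f <- scales[[m]] * hill_force(a, fk[[m]]$lm_norm, fk[[m]]$vm_norm,
                                    muscles[[m]])
      for (joint in intersect(names(muscles[[m]]$moment_arms),
                              c("sh_fe", "el_fe"))) {
        tau[[joint]] <- tau[[joint]] +
          muscle_torque(f, angles[[joint]], muscles[[m]], joint)
      }
    }
    tau
  }
  obj <- function(par) {
    scales <- stats::setNames(par[seq_along(mnames)], mnames)
    tau <- model_torque(scales, par[length(par)])
    sqrt(mean((tau$sh_fe[idx] - id_torques$sh_fe[idx])^2 +
                (tau$el_fe[idx] - id_torques$el_fe[idx])^2))
  }
  par0 <- c(rep(1, length(mnames)), -1.5)
  lower <- c(rep(0.5, length(mnames)), -3)
  upper <- c(rep(1.5, length(mnames)), -0.01)
  fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = maxit))
  list(scales = stats::setNames(fit$par[seq_along(mnames)], mnames),
       A = fit$par[length(fit$par)], rmse = fit$value,
       convergence = fit$convergence)
}
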