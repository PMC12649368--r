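#' Muscle model parameters
#'
#' Construct the parameter record for one Hill-type muscle: maximal isometric
#' force, optimal fiber length, pennation at optimal length, the activation
#' nonlinearity shape, and a quadratic moment-arm model per actuated joint.
#' Moment arms are signed with the flexion/abduction/external-rotation-positive
#' convention: a positive moment arm makes the muscle an agonist of the
#' positive joint direction.
#'
#' @param name Muscle identifier (e.g. `"BB"`).
#' @param F0m Maximal isometric force (N), positive.
#' @param l0 Optimal fiber length (m), positive.
#' @param phi0 Pennation angle at optimal fiber length (rad), in `[0, pi/2)`.
#' @param A Activation nonlinearity shape, in `[-3, 0)`.
#' @param moment_arms Named list, one entry per actuated joint (names from
#'   `c("sh_fe", "sh_aa", "sh_erir", "el_fe")`), each a numeric vector
#'   `c(c0, c1, c2)` of the quadratic `r(theta) = c0 + c1*theta + c2*theta^2`
#'   in metres. The first entry is the muscle's primary joint.
#' @param kp Passive force-length exponent (dimensionless).
#'
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, F0m, l0, phi0, moment_arms, A = -1.5, kp = 8) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(F0m), F0m > 0, is.finite(l0), l0 > 0,
            is.finite(phi0), phi0 >= 0, phi0 < pi / 2,
            is.finite(A), A >= -3, A < 0,
            is.list(moment_arms), length(moment_arms) >= 1L,
            !is.null(names(moment_arms)))
  bad <- setdiff(names(moment_arms), c("sh_fe", "sh_aa", "sh_erir", "el_fe"))
  if (length(bad)) stop("unknown joint(s) in moment_arms: ", paste(bad, collapse = ", "))
  moment_arms <- lapply(moment_arms, function(cf) {
    cf <- as.numeric(cf)
    length(cf) <- 3L
    cf[is.na(cf)] <- 0
    cf
  })
  structure(list(name = name, F0m = F0m, l0 = l0, phi0 = phi0, A = A, kp = kp,
                 moment_arms = moment_arms,
                 primary_joint = names(moment_arms)[1L]),
            class = "muscle_params")
}

#' Default seven-muscle set
#'
#' The seven muscles recorded in the hand-to-mouth protocol: brachioradialis
#' (BR), biceps brachii (BB), triceps brachii lateral head (TRL), anterior /
#' medial / posterior deltoid (AD, MD, PD) and pectoralis major (PM), with
#' literature-plausible maximal isometric forces, optimal fiber lengths,
#' pennation angles and quadratic moment-arm models on their actuated joints.
#' BB/BR/TRL act at the elbow (flexors positive, TRL extensor negative);
#' AD/PD act at shoulder flexion-extension; MD/PM at shoulder
#' abduction-adduction; PM and PD carry secondary internal/external rotation
#' moment arms so the rotation joint torque has contributors.
#'
#' @return Named list of [muscle_params()] objects.
#' @export
default_muscle_set <- function() {
  # F0m values are effective task-level maxima (roughly 40% of textbook
  # maximal isometric forces): the self-paced task then recruits a wide,
  # realistic fraction of the activation range, which keeps task-peak EMG
  # normalization well conditioned
  ms <- list(
    BR  = muscle_params("BR", F0m = 110,  l0 = 0.17, phi0 = 0,
                        moment_arms = list(el_fe = c(0.022, 0.008, -0.003))),
    BB  = muscle_params("BB", F0m = 250,  l0 = 0.12, phi0 = 0,
                        moment_arms = list(el_fe = c(0.030, 0.012, -0.005))),
    TRL = muscle_params("TRL", F0m = 290, l0 = 0.13, phi0 = 0.20,
                        moment_arms = list(el_fe = c(-0.022, -0.002, 0))),
    AD  = muscle_params("AD", F0m = 460, l0 = 0.15, phi0 = 0.17,
                        moment_arms = list(sh_fe = c(0.048, 0.006, -0.003))),
    MD  = muscle_params("MD", F0m = 90, l0 = 0.15, phi0 = 0.17,
                        moment_arms = list(sh_aa = c(0.035, 0.004, 0))),
    PD  = muscle_params("PD", F0m = 500, l0 = 0.16, phi0 = 0.17,
                        moment_arms = list(sh_fe = c(-0.045, 0.003, 0),
                                           sh_erir = c(0.012, 0, 0))),
    PM  = muscle_params("PM", F0m = 80, l0 = 0.15, phi0 = 0.30,
                        moment_arms = list(sh_aa = c(-0.040, -0.003, 0),
                                           sh_erir = c(-0.018, 0, 0)))
  )
  ms
}

#' Evaluate a muscle's moment arm at a joint
#'
#' @param params A [muscle_params()] object.
#' @param joint Joint id (`"sh_fe"`, `"sh_aa"`, `"sh_erir"`, `"el_fe"`).
#' @param theta Joint angle(s), rad.
#' @return Signed moment arm(s), m; zero if the muscle does not act there.
#' @export
moment_arm <- function(params, joint, theta) {
  cf <- params$moment_arms[[joint]]
  if (is.null(cf)) return(rep(0, length(theta)))
  cf[1] + cf[2] * theta + cf[3] * theta^2
}

# Antiderivative of the quadratic moment arm, for musculotendon excursion.
moment_arm_integral <- function(params, joint, theta) {
  cf <- params$moment_arms[[joint]]
  if (is.null(cf)) return(rep(0, length(theta)))
  cf[1] * theta + cf[2] * theta^2 / 2 + cf[3] * theta^3 / 3
}

#' Planar two-link arm model
#'
#' Inertial description of the upper arm (link 1) and forearm-plus-hand
#' (link 2) used by the simplified inverse dynamics: segment lengths, masses,
#' centre-of-mass offsets from the proximal joint, and moments of inertia
#' about the segment centre of mass. Defaults follow standard anthropometric
#' fractions of body mass and segment length.
#'
#' @param body_mass Body mass (kg).
#' @param upper_arm Upper-arm length (m).
#' @param forearm Forearm-plus-hand length (m).
#' @param m1,m2 Segment masses (kg); default anthropometric fractions.
#' @param c1,c2 Centre-of-mass offsets (m); default fractions of length.
#' @param I1,I2 Segment moments of inertia (kg m^2); default from radii of
#'   gyration.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(body_mass = 70, upper_arm = 0.31, forearm = 0.34,
                      m1 = 0.028 * body_mass, m2 = 0.022 * body_mass,
                      c1 = 0.436 * upper_arm, c2 = 0.682 * forearm,
                      I1 = m1 * (0.322 * upper_arm)^2,
                      I2 = m2 * (0.468 * forearm)^2,
                      g = 9.81) {
  vals <- c(body_mass = body_mass, upper_arm = upper_arm, forearm = forearm,
            m1 = m1, m2 = m2, c1 = c1, c2 = c2, I1 = I1, I2 = I2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all arm model parameters must be positive and finite")
  }
  structure(list(body_mass = body_mass, upper_arm = upper_arm,
                 forearm = forearm, m1 = m1, m2 = m2, c1 = c1, c2 = c2,
                 I1 = I1, I2 = I2, g = g),
            class = "arm_model")
}
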