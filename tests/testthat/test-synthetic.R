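test_that("minimum-jerk segments satisfy their boundary conditions", {
  p0 <- c(0, 0, 0); p1 <- c(1, 0, 0)
  n <- 401
  tr <- minimum_jerk_segment(p0, p1, T = 1, n = n)
  expect_equal(tr[1, ], p0)
  expect_equal(tr[n, ], p1)
  # midpoint symmetry of the quintic
  expect_equal(tr[(n + 1) / 2, 1], 0.5)
  # endpoint velocity and acceleration vanish
  v <- diff(tr[, 1]) * (n - 1)
  expect_lt(abs(v[1]), 1e-4)
  expect_lt(abs(v[n - 1]), 1e-4)

  # zero displacement: constant series
  cs <- minimum_jerk_segment(c(1, 2, 3), c(1, 2, 3), T = 2, n = 50)
  expect_true(all(apply(cs, 2, function(x) all(x == x[1]))))

  # direct polynomial evaluation at t = 0.25 of a 0.3 m reach
  tr2 <- minimum_jerk_segment(c(0, 0, 0), c(0.3, 0, 0), T = 1, n = 5)
  expect_equal(tr2[2, 1], 0.3 * (10 * 0.25^3 - 15 * 0.25^4 + 6 * 0.25^5),
               tolerance = 1e-12)
  expect_equal(tr2[2, 1], 0.0310546875, tolerance = 1e-9)

  expect_error(minimum_jerk_segment(c(0, NA, 0), p1, 1, 10), "finite")
  expect_error(minimum_jerk_segment(p0, p1, -1, 10), "positive")
})

test_that("trial generation is bit-identical under a fixed seed", {
  st1 <- quick_trial(seed = 11)
  st2 <- quick_trial(seed = 11)
  expect_identical(st1, st2)
  st3 <- quick_trial(seed = 12)
  expect_false(identical(st1$trial$emg, st3$trial$emg))
})

test_that("truth boundaries are ordered and sit at local speed minima", {
  st <- quick_trial(seed = 4)
  b <- st$truth_boundaries
  expect_true(all(diff(b) > 0))
  dur <- (nrow(st$trial$kin) - 1) / st$trial$fs_kin
  expect_true(all(b >= 0 & b <= dur))
  # interior boundaries (touches) fall in near-zero-speed dwells
  fs <- st$trial$fs_kin
  v <- sqrt(rowSums(apply(wrist_of(st), 2, diff)^2)) * fs
  vmax <- max(v)
  for (k in 2:4) {
    i <- round(b[k] * fs)
    expect_lt(v[i] / vmax, 0.08)
    expect_lt(v[i], v[i - 120])  # locally minimal vs +/- 300 ms
    expect_lt(v[i], v[i + 120])
  }
})

test_that("synthetic EMG is band-limited to 30-450 Hz", {
  st <- quick_trial(seed = 2)
  for (m in c("BB", "TRL", "PM")) {
    x <- st$trial$emg[, m]
    sp <- stats::spec.pgram(x, taper = 0, plot = FALSE)
    f <- sp$freq * st$trial$fs_emg
    out_band <- sum(sp$spec[f < 30 | f > 450]) / sum(sp$spec)
    expect_lt(out_band, 0.05)
  }
})

test_that("tremor strictly degrades elbow torque smoothness (same seed)", {
  geom <- task_geometry()
  base <- generate_trial(geom, impairment_profile(tremor_amplitude = 0),
                         seed = 3)
  trem <- generate_trial(geom, impairment_profile(tremor_amplitude = 0.05,
                                                  tremor_freq = 5.5),
                         seed = 3)
  sp <- function(st) {
    bi <- boundary_idx(st)
    sparc(elbow_id_torque(st)[bi[2]:bi[3]], st$trial$fs_kin)
  }
  expect_lt(sp(trem), sp(base))
  # stronger tremor, stronger degradation
  trem2 <- generate_trial(geom, impairment_profile(tremor_amplitude = 0.2,
                                                   tremor_freq = 5.5),
                          seed = 3)
  expect_lt(sp(trem2), sp(trem))
})

test_that("co-activation level raises the TRL/BB co-contraction index", {
  geom <- task_geometry()
  tc <- function(coact) {
    st <- generate_trial(geom, impairment_profile(coactivation_level = coact),
                         seed = 6, keep_internals = TRUE)
    act <- st$truth_activation
    muscles <- default_muscle_set()
    tau <- sapply(c("TRL", "BB"), function(m) {
      fk <- fiber_kinematics(st$truth_angles, muscles[[m]], fs = 400)
      muscle_torque(hill_force(act[, m], fk$lm_norm, fk$vm_norm, muscles[[m]]),
                    st$truth_angles$el_fe, muscles[[m]])
    })
    bi <- boundary_idx(st)
    tcci(tau[, "BB"], tau[, "TRL"], 400, c(bi[2], bi[3]),
         max_ag = max(abs(tau[bi[1]:bi[5], "BB"])),
         max_ant = max(abs(tau[bi[1]:bi[5], "TRL"])))
  }
  expect_lt(tc(0.05), tc(0.20))
})

test_that("cohort counts, group structure, and severity links hold", {
  co <- generate_cohort(n_per_group = 3, seed = 9, keep_trials = TRUE)
  expect_length(co$manifest$subjects, 6L)
  expect_equal(sum(lengths(co$trials)), 30L)
  groups <- vapply(co$manifest$subjects, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("healthy", "stroke")]), c(3L, 3L),
               ignore_attr = TRUE)

  plan <- generate_cohort(n_per_group = 20, seed = 13,
                          keep_trials = FALSE)$manifest
  coact <- vapply(plan$subjects, function(s) s$profile$coactivation_level, 1)
  sev <- vapply(plan$subjects, function(s) as.numeric(s$severity_score), 1)
  stroke <- vapply(plan$subjects, `[[`, "", "group") == "stroke"
  expect_gt(mean(coact[stroke]), mean(coact[!stroke]))
  # injected severity is inversely related to coactivation in the stroke group
  expect_lt(cor(sev[stroke], coact[stroke], method = "spearman"), 0)
  expect_gt(cor(sev[stroke],
                vapply(plan$subjects[stroke], function(s)
                  s$profile$force_scale, 1),
                method = "spearman"), 0)
})

test_that("unreachable geometry is rejected", {
  geom <- task_geometry(upper_arm = 0.2, forearm = 0.2, target_frac = 1.2)
  expect_error(generate_trial(geom, healthy_profile(), seed = 1),
               "unreachable")
})
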