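# Shared fixtures. The full synthetic cohort and its pipeline run are costly,
# so they are built once per session and reused across test files.

.htm_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.htm_cache$run)) {
    .htm_cache$run <- run_pipeline(
      pipeline_config(n_per_group = 20, seed = 101), progress = FALSE)
  }
  .htm_cache$run
}

comparison_row <- function(run, metric, window) {
  cmp <- run$comparisons
  cmp[cmp$metric == metric & cmp$window == window, ]
}

quick_trial <- function(seed = 1, profile = healthy_profile(),
                        geom = task_geometry(), ...) {
  generate_trial(geom, profile, seed = seed, ...)
}

wrist_of <- function(st) st$trial$kin[c("wrist_x", "wrist_y", "wrist_z")]

# elbow net torque (inverse dynamics) of a synthetic trial, smoothed angles
elbow_id_torque <- function(st, smooth_hz = 8) {
  fs <- st$trial$fs_kin
  lp <- function(x) {
    bf <- signal::butter(2, smooth_hz / (fs / 2), type = "low")
    n <- length(x); p <- min(n - 1L, ceiling(fs / 2))
    xp <- c(x[(p + 1):2], x, x[(n - 1):(n - p)])
    as.numeric(signal::filtfilt(bf, xp))[(p + 1):(p + n)]
  }
  q1 <- lp(st$trial$kin$sh_fe)
  q2 <- lp(st$trial$kin$el_fe)
  inverse_dynamics_2link(q1, q2, fs)$el_fe
}

boundary_idx <- function(st) {
  round(as.numeric(st$truth_boundaries) * st$trial$fs_kin) + 1L
}
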