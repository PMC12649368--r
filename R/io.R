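htm_trial_cols <- function() {
  c("time_s", paste0("emg_", htm_muscle_labels),
    "wrist_x", "wrist_y", "wrist_z", "sh_fe", "sh_aa", "sh_erir", "el_fe")
}

#' Write / read a trial CSV
#'
#' One CSV per trial on the 2000 Hz EMG time base: columns `time_s`, the seven
#' EMG channels (V), wrist position (m) and the four joint angles (rad).
#' Kinematic columns are populated on every fifth row (the 400 Hz grid) and
#' empty elsewhere. The round trip is lossless to full double precision.
#'
#' @param trial An `htm_trial` (or the `trial` element of a synthetic trial).
#' @param path Output CSV path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns an `htm_trial`.
#' @export
write_trial_csv <- function(trial, path) {
  if (inherits(trial, "htm_synthetic_trial")) trial <- trial$trial
  stopifnot(inherits(trial, "htm_trial"))
  n_emg <- nrow(trial$emg)
  fac <- trial$fs_emg / trial$fs_kin
  df <- data.table::data.table(time_s = (seq_len(n_emg) - 1) / trial$fs_emg)
  for (m in colnames(trial$emg)) df[[paste0("emg_", m)]] <- trial$emg[, m]
  for (cn in c("wrist_x", "wrist_y", "wrist_z", "sh_fe", "sh_aa",
               "sh_erir", "el_fe")) {
    col <- rep(NA_real_, n_emg)
    col[seq(1, n_emg, by = fac)] <- trial$kin[[cn]]
    df[[cn]] <- col
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- data.table::fread(path)
  want <- htm_trial_cols()
  if (!identical(sort(names(df)), sort(want))) {
    stop("trial file ", path, " has columns {",
         paste(names(df), collapse = ", "), "}; expected {",
         paste(want, collapse = ", "), "}")
  }
  kin_rows <- which(!is.na(df$wrist_x))
  fac <- unique(diff(kin_rows))
  if (length(fac) != 1L) stop("inconsistent kinematic sampling in ", path)
  dt <- stats::median(diff(df$time_s))
  fs_emg <- round(1 / dt)
  emg <- as.matrix(df[, paste0("emg_", htm_muscle_labels), with = FALSE])
  colnames(emg) <- htm_muscle_labels
  kin <- data.frame(time_s = df$time_s[kin_rows],
                    wrist_x = df$wrist_x[kin_rows],
                    wrist_y = df$wrist_y[kin_rows],
                    wrist_z = df$wrist_z[kin_rows],
                    sh_fe = df$sh_fe[kin_rows], sh_aa = df$sh_aa[kin_rows],
                    sh_erir = df$sh_erir[kin_rows], el_fe = df$el_fe[kin_rows])
  structure(list(emg = emg, kin = kin, fs_emg = fs_emg,
                 fs_kin = fs_emg / fac, meta = list()),
            class = "htm_trial")
}

#' Write / read a cohort manifest (JSON)
#'
#' The manifest records every subject's group label, anthropometry, severity
#' score, impairment profile, per-trial generation parameters and (when
#' available) trial file paths, so a cohort is exactly reconstructible.
#'
#' @param manifest A cohort manifest from [generate_cohort()].
#' @param path JSON path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest list.
#' @export
write_manifest <- function(manifest, path) {
  manifest$subjects <- lapply(manifest$subjects, function(sub) {
    sub$profile <- unclass(sub$profile)
    sub
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  man$subjects <- lapply(man$subjects, function(sub) {
    sub$profile <- do.call(impairment_profile, sub$profile[
      c("force_scale", "coactivation_level", "tremor_amplitude",
        "tremor_freq", "duration_scale", "severity_score")])
    missing <- setdiff(c("id", "group", "body_mass", "upper_arm", "forearm"),
                       names(sub))
    if (length(missing)) {
      stop("manifest subject record lacks field(s): ",
           paste(missing, collapse = ", "))
    }
    sub
  })
  man
}
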