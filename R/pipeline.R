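#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with validated defaults.
#' All randomness downstream derives from `seed`.
#'
#' @param n_per_group Subjects per group in the synthetic cohort.
#' @param seed Master seed.
#' @param n_trials Trials per subject.
#' @param alpha Significance level for group tests and feature selection.
#' @param fdr_policy FDR family policy, see [fdr_adjust()].
#' @param k_folds Cross-validation folds.
#' @param max_features Cap on features entering the classifiers (ranked by
#'   adjusted p).
#' @param smooth_hz Zero-phase low-pass cutoff (Hz) for measured kinematics
#'   entering the torque chain.
#' @param calibrate If `TRUE`, per-subject F0m scale calibration on the first
#'   trial is applied before feature extraction.
#' @param sparc A [sparc_params()].
#' @param seg A [segment_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 20, seed = 1L, n_trials = 5,
                            alpha = 0.05, fdr_policy = "per-window",
                            k_folds = 5, max_features = 20, smooth_hz = 8,
                            calibrate = FALSE, sparc = sparc_params(),
                            seg = segment_config(), out_dir = NULL) {
  cfg <- list(n_per_group = n_per_group, seed = seed, n_trials = n_trials,
              alpha = alpha, fdr_policy = fdr_policy, k_folds = k_folds,
              max_features = max_features, smooth_hz = smooth_hz,
              calibrate = calibrate, sparc = sparc, seg = seg,
              out_dir = out_dir)
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param x A named list of configuration fields (e.g. parsed from YAML/JSON).
#' @export
as_pipeline_config <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

validate_pipeline_config <- function(cfg) {
  required <- c("n_per_group", "seed", "n_trials", "alpha", "fdr_policy",
                "k_folds", "max_features", "smooth_hz", "calibrate",
                "sparc", "seg")
  missing <- required[!required %in% names(cfg) |
                        vapply(cfg[required], is.null, TRUE)]
  missing <- missing[!is.na(missing)]
  if (length(missing)) {
    stop("configuration is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(cfg$n_per_group >= 2, cfg$n_trials >= 4, cfg$alpha > 0,
            cfg$alpha < 1, cfg$k_folds >= 2, cfg$smooth_hz > 0)
  structure(cfg, class = "pipeline_config")
}

# Full signal chain for one subject: returns the trials x 130 metric matrix,
# detected and true boundaries, or an error reason.
process_subject <- function(sub, cfg, muscles = default_muscle_set()) {
  arm <- arm_model(body_mass = sub$body_mass, upper_arm = sub$upper_arm,
                   forearm = sub$forearm)
  syn <- lapply(sub$trials, function(tr) materialize_trial(sub, tr))
  # per-subject task-peak normalization across the five trials
  envs <- lapply(syn, function(st) {
    apply(st$trial$emg, 2, emg_envelope, fs = st$trial$fs_emg)
  })
  task_peak <- apply(do.call(rbind, lapply(envs, function(e)
    apply(e, 2, max))), 2, max)
  scales <- stats::setNames(rep(1, length(muscles)), names(muscles))
  shape_A <- NULL
  result <- tryCatch({
    procs <- vector("list", length(syn))
    for (i in seq_along(syn)) {
      st <- syn[[i]]
      fs_kin <- st$trial$fs_kin
      ang <- st$trial$kin[c("sh_fe", "sh_aa", "sh_erir", "el_fe")]
      ang[] <- lapply(ang, lowpass_zp, fs = fs_kin, fc = cfg$smooth_hz)
      n <- nrow(ang)
      a400 <- u400 <- matrix(0, n, length(muscles),
                             dimnames = list(NULL, names(muscles)))
      for (m in names(muscles)) {
        e <- normalize_excitation(envs[[i]][, m], task_peak[[m]])
        ad <- activation_dynamics(e, st$trial$fs_emg, A = muscles[[m]]$A)
        a400[, m] <- align_rates(ad$a)
        u400[, m] <- align_rates(ad$u)
      }
      if (cfg$calibrate && i == 1L) {
        idt <- inverse_dynamics_2link(ang$sh_fe, ang$el_fe, fs_kin, arm)
        cal <- calibrate_muscles(u400, ang, idt, muscles, arm)
        scales <- cal$scales
        shape_A <- cal$A
      }
      force <- cvel <- mtau <- matrix(0, n, length(muscles),
                                      dimnames = list(NULL, names(muscles)))
      # dynamics-based net torques for the sagittal joint pair; the
      # abduction-adduction and rotation joints have no two-link reference
      # and use the summed muscle-model torques instead
      idt <- inverse_dynamics_2link(ang$sh_fe, ang$el_fe, fs_kin, arm)
      jt <- list(sh_fe = idt$sh_fe, el_fe = idt$el_fe,
                 sh_aa = NULL, sh_erir = NULL)
      for (m in names(muscles)) {
        fk <- fiber_kinematics(muscles[[m]], angles = ang, fs = fs_kin)
        a <- if (is.null(shape_A)) a400[, m] else
          shape_nonlinearity(u400[, m], shape_A)
        force[, m] <- scales[[m]] *
          hill_force(a, fk$lm_norm, fk$vm_norm, muscles[[m]])
        cvel[, m] <- -fk$vm_norm * 10 * muscles[[m]]$l0
        mtau[, m] <- muscle_torque(force[, m],
                                   ang[[muscles[[m]]$primary_joint]],
                                   muscles[[m]])
        for (joint in intersect(names(muscles[[m]]$moment_arms),
                                c("sh_aa", "sh_erir"))) {
          contrib <- muscle_torque(force[, m], ang[[joint]], muscles[[m]],
                                   joint)
          jt[[joint]] <- if (is.null(jt[[joint]])) contrib else
            jt[[joint]] + contrib
        }
      }
      procs[[i]] <- list(
        fs_kin = fs_kin, angles = ang,
        ang_vel = lapply(ang, deriv_c, fs = fs_kin),
        force = force, contraction_vel = cvel, muscle_torque = mtau,
        joint_torque = jt,
        boundaries = segment_phases(
          st$trial$kin[c("wrist_x", "wrist_y", "wrist_z")], fs_kin, cfg$seg),
        truth = st$truth_boundaries)
    }
    metrics <- do.call(rbind, lapply(procs, function(p)
      trial_metrics(p, p$boundaries, sub$body_mass, cfg$sparc)))
    list(id = sub$id, group = sub$group, severity = sub$severity_score,
         metrics = metrics,
         boundaries = lapply(procs, `[[`, "boundaries"),
         truth = lapply(procs, `[[`, "truth"),
         calibration = if (cfg$calibrate) list(scales = scales, A = shape_A),
         error = NULL)
  }, error = function(e) {
    list(id = sub$id, group = sub$group, severity = sub$severity_score,
         error = conditionMessage(e))
  })
  result
}

#' Run the full analysis pipeline
#'
#' Generates (or re-generates, deterministically) the synthetic cohort,
#' processes every trial through the EMG-to-torque chain, segments the
#' movement, extracts the 130 phase-windowed features, runs the group
#' statistics with FDR control and the severity correlations, selects
#' discriminative features, and cross-validates the five classifiers on the
#' phase-specific and the whole-task-only feature sets. Rerunning with the
#' same configuration reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-stage progress.
#' @return Object of class `htm_run_report`: list with `feature_table`,
#'   `comparisons`, `correlations`, `selection`, `cv_phase`, `cv_whole`,
#'   `segmentation`, `exclusions`, `timings` (s), and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = interactive()) {
  config <- validate_pipeline_config(config)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  plan <- cohort_plan(config$n_per_group, config$seed, config$n_trials)
  timings["plan"] <- tic() - t0

  t0 <- tic()
  subject_results <- lapply(plan$subjects, function(sub) {
    if (progress) message("processing ", sub$id)
    process_subject(sub, config)
  })
  timings["process"] <- tic() - t0

  t0 <- tic()
  ft <- extract_features(subject_results)
  ok <- subject_results[vapply(subject_results, function(r)
    is.null(r$error), TRUE)]
  seg_eval <- evaluate_segmentation(
    unlist(lapply(ok, `[[`, "boundaries"), recursive = FALSE),
    unlist(lapply(ok, `[[`, "truth"), recursive = FALSE))
  cmp <- compare_groups(ft, alpha = config$alpha,
                        fdr_policy = config$fdr_policy)
  corr <- if (sum(ft$group == "stroke" & !is.na(ft$severity)) >= 5) {
    severity_correlation(ft)
  } else {
    message("severity correlations skipped: fewer than 5 stroke participants")
    NULL
  }
  sel <- select_features(cmp, alpha = config$alpha)
  timings["stats"] <- tic() - t0

  t0 <- tic()
  run_cv <- function(ids) {
    if (!length(ids)) return(NULL)
    if (min(table(ft$group)) < config$k_folds) {
      message("classification skipped: fewer samples per class than folds")
      return(NULL)
    }
    cross_validate(as.matrix(ft[, ids, drop = FALSE]), ft$group,
                   k = config$k_folds, seed = config$seed,
                   max_features = config$max_features)
  }
  cv_phase <- run_cv(sel$phase_specific)
  cv_whole <- run_cv(sel$whole_task)
  timings["classify"] <- tic() - t0

  report <- structure(list(
    feature_table = ft, comparisons = cmp, correlations = corr,
    selection = sel, cv_phase = cv_phase, cv_whole = cv_whole,
    segmentation = seg_eval, exclusions = attr(ft, "exclusions"),
    timings = timings, manifest = plan, config = config),
    class = "htm_run_report")
  if (!is.null(config$out_dir)) write_outputs(report, config$out_dir)
  report
}

#' Write the tabular pipeline outputs
#'
#' Feature table, group comparisons, severity correlations, classifier
#' reports and segmentation evaluation as CSV, plus the cohort manifest as
#' JSON.
#'
#' @param report An `htm_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$feature_table, file.path(dir, "feature_table.csv"))
  data.table::fwrite(report$comparisons, file.path(dir, "group_comparisons.csv"))
  if (!is.null(report$correlations)) {
    data.table::fwrite(report$correlations,
                       file.path(dir, "severity_correlations.csv"))
  }
  if (!is.null(report$cv_phase)) {
    data.table::fwrite(report$cv_phase, file.path(dir, "classifiers_phase_specific.csv"))
  }
  if (!is.null(report$cv_whole)) {
    data.table::fwrite(report$cv_whole, file.path(dir, "classifiers_whole_task.csv"))
  }
  seg <- report$segmentation
  data.table::fwrite(data.frame(mae_ms = seg$mae, rmse_ms = seg$rmse,
                                icc = seg$icc),
                     file.path(dir, "segmentation_accuracy.csv"))
  write_manifest(report$manifest, file.path(dir, "cohort_manifest.json"))
  invisible(dir)
}

#' @export
print.htm_run_report <- function(x, ...) {
  ft <- x$feature_table
  cat("Hand-to-mouth phase-specific biomechanics run\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(ft),
              paste(sprintf("%s=%d", names(table(ft$group)), table(ft$group)),
                    collapse = ", ")))
  cat(sprintf("  segmentation: MAE %.1f ms, RMSE %.1f ms, ICC %.3f\n",
              x$segmentation$mae, x$segmentation$rmse, x$segmentation$icc))
  cat(sprintf("  significant features: %d phase-specific, %d whole-task\n",
              length(x$selection$phase_specific),
              length(x$selection$whole_task)))
  if (!is.null(x$cv_phase)) {
    cat("  cross-validated accuracy (phase-specific features):\n")
    for (i in seq_len(nrow(x$cv_phase))) {
      cat(sprintf("    %-5s %.3f (AUC %.3f)\n", x$cv_phase$model[i],
                  x$cv_phase$accuracy[i], x$cv_phase$auc[i]))
    }
  }
  invisible(x)
}
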