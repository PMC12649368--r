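#' Benjamini-Hochberg FDR adjustment with a family policy
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' applied either within each phase-window family (default, matching the
#' per-window structure of the metric tables) or globally.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param policy `"per-window"` or `"global"`.
#' @param windows Window label per p-value; required for `"per-window"`.
#' @return Adjusted p-values, same order as `p`.
#' @export
fdr_adjust <- function(p, policy = c("per-window", "global"), windows = NULL) {
  policy <- match.arg(policy)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  if (policy == "global" || is.null(windows)) {
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
  } else {
    if (length(windows) != length(p)) stop("windows must match p in length")
    for (w in unique(windows)) {
      sel <- ok & windows == w
      out[sel] <- stats::p.adjust(p[sel], method = "BH")
    }
  }
  out
}

fmt_mean_sd <- function(x) sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
fmt_median_iqr <- function(x) sprintf("%.3g (%.3g)", stats::median(x),
                                      stats::IQR(x))

#' Between-group comparison of every feature
#'
#' For every metric-by-window feature: Shapiro-Wilk normality per group at
#' alpha 0.05; Welch t-test when both groups pass, Mann-Whitney U otherwise
#' (two-sided); summaries formatted as mean +/- SD or median (IQR) to match
#' the routing; Benjamini-Hochberg FDR adjustment within each window family
#' (policy configurable). Features with zero variance in both groups are
#' skipped with a reason.
#'
#' @param ft A `feature_table` from [extract_features()] (or any data frame
#'   with a `group` column and numeric feature columns named
#'   `Metric__Window`).
#' @param alpha Significance level applied to adjusted p-values.
#' @param fdr_policy Family policy for [fdr_adjust()].
#' @return Data frame of class `group_comparison`: metric, window, test, group
#'   summaries, group means, raw and adjusted p, significance flag, and the
#'   direction (sign of stroke minus healthy mean).
#' @export
compare_groups <- function(ft, alpha = 0.05,
                           fdr_policy = c("per-window", "global")) {
  fdr_policy <- match.arg(fdr_policy)
  feats <- setdiff(names(ft), c("subject", "group", "severity"))
  g <- ft$group
  if (!all(c("healthy", "stroke") %in% g)) {
    stop("feature table must contain both 'healthy' and 'stroke' rows")
  }
  if (min(table(g)) < 3) stop("need at least 3 participants per group")
  rows <- lapply(feats, function(f) {
    parts <- strsplit(f, "__", fixed = TRUE)[[1]]
    x <- ft[[f]][g == "healthy"]
    y <- ft[[f]][g == "stroke"]
    base <- data.frame(metric = parts[1], window = parts[2],
                       mean_healthy = mean(x), mean_stroke = mean(y),
                       direction = sign(mean(y) - mean(x)),
                       stringsAsFactors = FALSE)
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
      return(cbind(base, test = "skipped", summary_healthy = NA,
                   summary_stroke = NA, p = NA_real_,
                   reason = "zero variance"))
    }
    normal <- stats::shapiro.test(x)$p.value > 0.05 &&
      stats::shapiro.test(y)$p.value > 0.05
    if (normal) {
      p <- stats::t.test(x, y)$p.value
      cbind(base, test = "t", summary_healthy = fmt_mean_sd(x),
            summary_stroke = fmt_mean_sd(y), p = p, reason = NA)
    } else {
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      cbind(base, test = "mann-whitney", summary_healthy = fmt_median_iqr(x),
            summary_stroke = fmt_median_iqr(y), p = p, reason = NA)
    }
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- fdr_adjust(res$p, policy = fdr_policy,
                               windows = res$window)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  class(res) <- c("group_comparison", class(res))
  res
}

#' Percent reduction between group summaries
#'
#' Relative reduction of the impaired-group magnitude with respect to the
#' reference-group magnitude, in percent.
#'
#' @param reference,impaired Group summary values (same sign).
#' @return `100 * (|reference| - |impaired|) / |reference|`.
#' @export
percent_reduction <- function(reference, impaired) {
  100 * (abs(reference) - abs(impaired)) / abs(reference)
}

#' Default metric selection for severity correlations
#'
#' Elbow F/E work, biceps brachii work, anterior deltoid work, SPARC of elbow
#' F/E and shoulder Ab/Ad torque, and TCCI of the AD/PD and TRL/BB pairs.
#'
#' @return Character vector of metric ids.
#' @export
severity_metrics_default <- function() {
  c("Work_ElFE", "Work_BB", "Work_AD", "Sparc_ElFE", "Sparc_ShAA",
    "TCCI_AD_PD", "TCCI_TRL_BB")
}

#' Spearman correlation of features with the severity score
#'
#' Rank correlations between the motor severity score and a selected subset
#' of metrics across all five windows, within the stroke group, with
#' Benjamini-Hochberg adjustment over the resulting table.
#'
#' @param ft A `feature_table`.
#' @param metrics Metric ids to correlate; default
#'   [severity_metrics_default()].
#' @return Data frame: metric, window, rho, p, adjusted p, significance flag.
#' @export
severity_correlation <- function(ft, metrics = severity_metrics_default()) {
  sel <- ft$group == "stroke" & !is.na(ft$severity)
  if (sum(sel) < 5) stop("fewer than 5 stroke participants with severity")
  sev <- ft$severity[sel]
  rows <- list()
  for (m in metrics) {
    for (w in htm_windows) {
      f <- paste0(m, "__", w)
      if (!f %in% names(ft)) next
      ct <- suppressWarnings(
        stats::cor.test(ft[[f]][sel], sev, method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, window = w, rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- fdr_adjust(res$p, policy = "global")
  res$significant <- res$p_adjusted < 0.05
  res
}
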