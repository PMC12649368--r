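#' Select discriminative features from the group comparison
#'
#' Features with an FDR-adjusted p-value below `alpha` are retained, ranked by
#' adjusted p. Two sets are returned: the phase-specific set (significant
#' features from all windows, subphases plus whole task) and the
#' whole-task-only set.
#'
#' @param comparison A `group_comparison` from [compare_groups()].
#' @param alpha Selection level on adjusted p-values.
#' @return List with character vectors `phase_specific` and `whole_task`
#'   of `Metric__Window` feature ids (either may be empty, with a warning).
#' @export
select_features <- function(comparison, alpha = 0.05) {
  sig <- comparison[comparison$significant %in% TRUE, ]
  sig <- sig[order(sig$p_adjusted), ]
  ids <- if (nrow(sig)) paste0(sig$metric, "__", sig$window) else character(0)
  out <- list(phase_specific = ids,
              whole_task = ids[sig$window == "Whole"])
  for (s in names(out)) {
    if (!length(out[[s]])) {
      warning("empty feature selection for set '", s,
              "'; classification will be skipped")
    }
  }
  out
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 from integer counts, with the
#' convention that a ratio with zero denominator is 0; optionally the AUC of
#' pooled scores via the rank (Mann-Whitney) statistic.
#'
#' @param cm Named counts `c(TP =, FP =, FN =, TN =)`.
#' @param scores Optional classifier scores (higher = more positive-class).
#' @param labels Optional true labels (logical or 0/1) aligned with `scores`.
#' @return Named vector: accuracy, precision, recall, f1 and (if scores are
#'   given) auc.
#' @export
classifier_metrics <- function(cm, scores = NULL, labels = NULL) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(cm)), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  out <- c(accuracy = (tp + tn) / total, precision = prec, recall = rec,
           f1 = f1)
  if (!is.null(scores)) {
    out <- c(out, auc = auc_rank(scores, labels))
  }
  out
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic of
#' the scores; ties receive midranks. Invariant under strictly monotone
#' transformations of the score.
#'
#' @param scores Numeric scores, higher = more positive-class.
#' @param labels Logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Median-heuristic kernel scale: gamma = 1 / median pairwise squared distance.
median_gamma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  md <- stats::median(d2[d2 > 0])
  if (!is.finite(md) || md <= 0) md <- 1
  1 / md
}

fit_predict_model <- function(model, xtr, ytr, xte, seed) {
  pos <- "stroke"
  switch(model,
    QSVM = ,
    GSVM = {
      kern <- if (model == "QSVM") "polynomial" else "radial"
      fit <- e1071::svm(x = xtr, y = ytr, kernel = kern, degree = 2,
                        coef0 = 1, cost = 1, gamma = median_gamma(xtr),
                        scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      score <- if (first == pos) dv[, 1] else -dv[, 1]
      list(pred = as.character(pr), score = as.numeric(score))
    },
    LR = {
      df <- data.frame(xtr, check.names = FALSE)
      df$.y <- as.integer(ytr == pos)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      p <- suppressWarnings(
        stats::predict(fit, data.frame(xte, check.names = FALSE),
                       type = "response"))
      list(pred = ifelse(p > 0.5, pos, "healthy"), score = as.numeric(p))
    },
    LD = {
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr, tol = 1e-8))
      pr <- stats::predict(fit, xte)
      list(pred = as.character(pr$class), score = pr$posterior[, pos])
    },
    SD = {
      d <- ncol(xtr)
      nsub <- ceiling(d / 2)
      post <- matrix(NA_real_, nrow(xte), 30)
      for (b in seq_len(30)) {
        idx <- sample.int(d, nsub)
        fit <- tryCatch(
          suppressWarnings(MASS::lda(xtr[, idx, drop = FALSE],
                                     grouping = ytr, tol = 1e-8)),
          error = function(e) NULL)
        if (is.null(fit)) next
        post[, b] <- stats::predict(fit, xte[, idx, drop = FALSE])$posterior[, pos]
      }
      p <- rowMeans(post, na.rm = TRUE)
      p[!is.finite(p)] <- 0.5
      votes <- rowMeans(post > 0.5, na.rm = TRUE)
      list(pred = ifelse(votes > 0.5, pos, "healthy"), score = p)
    },
    stop("unknown model '", model, "'")
  )
}

#' Cross-validated classification of stroke vs healthy
#'
#' Stratified k-fold cross-validation of five classifiers: SVM with quadratic
#' polynomial kernel (QSVM), SVM with Gaussian kernel (GSVM), logistic
#' regression (LR), a random-subspace ensemble of 30 linear discriminants
#' (SD), and a single linear discriminant (LD). Within each fold, features
#' are z-scored with statistics fit on the training folds only; SVM kernel
#' scales use the median heuristic on the training data; no hyperparameters
#' are tuned. Test-fold predictions are pooled into one confusion matrix and
#' one rank-statistic AUC per model.
#'
#' @param x Numeric feature matrix (participants x features).
#' @param y Group labels (`"healthy"` / `"stroke"`); stroke is the positive
#'   class.
#' @param models Subset of `c("QSVM", "GSVM", "LR", "SD", "LD")`.
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and subspace sampling.
#' @param max_features Optional cap on the number of feature columns used
#'   (first columns kept, i.e. the strongest when the matrix is ordered by
#'   selection rank); keeps the discriminant models well-posed when many
#'   features pass selection.
#' @return Object of class `classifier_report`: data frame (model, accuracy,
#'   precision, recall, f1, auc, n_evaluated) with fold assignments, the
#'   feature names used, and the seed as attributes.
#' @export
cross_validate <- function(x, y, models = c("QSVM", "GSVM", "LR", "SD", "LD"),
                           k = 5, seed = 1L, max_features = NULL) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("healthy", "stroke"))
  stopifnot(nrow(x) == length(y))
  if (!is.null(max_features) && ncol(x) > max_features) {
    x <- x[, seq_len(max_features), drop = FALSE]
  }
  if (min(table(y)) < k) stop("need at least k samples per class for ",
                              "stratified ", k, "-fold CV")
  with_seed(seed, {
    folds <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    pred <- matrix(NA_character_, length(y), length(models),
                   dimnames = list(NULL, models))
    score <- matrix(NA_real_, length(y), length(models),
                    dimnames = list(NULL, models))
    for (fold in seq_len(k)) {
      te <- which(folds == fold)
      tr <- which(folds != fold)
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
        stop("a class is absent from fold ", fold)
      }
      mu <- colMeans(x[tr, , drop = FALSE])
      sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sg[sg < 1e-12] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
      for (model in models) {
        fp <- fit_predict_model(model, xtr, y[tr], xte, seed)
        pred[te, model] <- fp$pred
        score[te, model] <- fp$score
      }
    }
    lab <- y == "stroke"
    rows <- lapply(models, function(model) {
      p <- pred[, model] == "stroke"
      cm <- c(TP = sum(p & lab), FP = sum(p & !lab),
              FN = sum(!p & lab), TN = sum(!p & !lab))
      met <- classifier_metrics(cm, scores = score[, model], labels = lab)
      data.frame(model = model, t(met), n_evaluated = length(y))
    })
    rep <- do.call(rbind, rows)
    attr(rep, "folds") <- folds
    attr(rep, "features") <- colnames(x)
    attr(rep, "seed") <- seed
    class(rep) <- c("classifier_report", class(rep))
    rep
  })
}
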