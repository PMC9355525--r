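#' @title Operating characteristics, ROC/DeLong inference, Brier, bootstrap
#' @description Everything needed to score a prognostic rule or risk model
#'   against binary outcomes: confusion counts, sensitivity/specificity, the
#'   Mann-Whitney AUROC with midrank tie handling, DeLong variance and paired
#'   AUROC comparison from placement values, the Brier score, and seeded
#'   bootstrap internal validation.
#' @name evaluation
NULL

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; at least one must be
#'   positive.
#' @return List of class \code{"confusion"}.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(cnt) == 0) stop("empty cohort: all confusion counts are zero")
  structure(as.list(cnt), class = "confusion")
}

#' Confusion of a binary prediction against binary truth
#' @param predicted,actual Logical (or 0/1) vectors of equal length.
#' @export
confusion_from_predictions <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  if (length(predicted) != length(actual)) stop("length mismatch")
  confusion_from_counts(sum(predicted & actual), sum(predicted & !actual),
                        sum(!predicted & !actual), sum(!predicted & actual))
}

#' Sensitivity and specificity of a confusion
#' @param cm A \code{\link{confusion_from_counts}} result.
#' @return Named numeric vector (sensitivity, specificity), as proportions.
#' @export
sens_spec <- function(cm) {
  if (cm$tp + cm$fn == 0) stop("no positives: sensitivity undefined")
  if (cm$tn + cm$fp == 0) stop("no negatives: specificity undefined")
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp))
}

#' AUROC of a dichotomous rule
#'
#' A binary rule's ROC has a single interior point, so the trapezoidal area
#' reduces to (sensitivity + specificity) / 2.
#'
#' @param sensitivity,specificity Proportions in [0, 1].
#' @export
binary_rule_auroc <- function(sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both outcome classes must be present")
  }
  labels
}

#' Mann-Whitney AUROC
#'
#' U-statistic estimator with half credit for tied scores; identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores (higher = more at risk).
#' @param labels Binary outcomes (TRUE/1 = event).
#' @export
auroc_mann_whitney <- function(scores, labels) {
  labels <- check_two_classes(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  # midrank formulation: O(n log n) and exactly the pair-count U statistic
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Empirical ROC curve
#'
#' @inheritParams auroc_mann_whitney
#' @return Data frame (threshold, fpr, tpr) ordered from the all-negative to
#'   the all-positive corner; the first row is the (0, 0) corner.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(cut) {
    pred <- scores >= cut
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half); and symmetrically for negatives.
placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUROC with a DeLong confidence interval
#'
#' Variance from the structural-components (placement-value) estimator:
#' var = S10/m + S01/n where S10, S01 are the sample variances of the
#' positive and negative placement values.
#'
#' @inheritParams auroc_mann_whitney
#' @param level Confidence level (default 0.95); 0 gives a zero-width CI at
#'   the point estimate.
#' @param logit_ci If TRUE the CI is formed on the logit scale and mapped
#'   back (never leaves (0,1)); default is the normal scale truncated to
#'   [0, 1].
#' @return List of class \code{"roc_result"}: \code{auroc}, \code{var},
#'   \code{ci} (lo, hi), \code{roc} (the \code{\link{roc_curve}} points),
#'   \code{n_pos}, \code{n_neg}.
#' @export
delong_ci <- function(scores, labels, level = 0.95, logit_ci = FALSE) {
  labels <- check_two_classes(labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    stop("DeLong variance needs at least 2 observations per class")
  }
  pl <- placements(scores, labels)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  z <- if (level <= 0) 0 else stats::qnorm(1 - (1 - level) / 2)
  auc <- pl$auc
  if (logit_ci && v > 0 && auc > 0 && auc < 1) {
    lg <- stats::qlogis(auc)
    se_lg <- sqrt(v) / (auc * (1 - auc))
    ci <- stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
  } else {
    ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  }
  structure(list(auroc = auc, var = v, ci = c(lo = ci[1], hi = ci[2]),
                 roc = roc_curve(scores, labels),
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}

#' Paired DeLong comparison of two AUROCs
#'
#' Both score vectors must be evaluated on the same patients in the same
#' order.  The z statistic uses the DeLong covariance of the two placement
#' vectors; p is the two-sided normal tail.
#'
#' @param scores_a,scores_b Paired risk scores.
#' @param labels Binary outcomes shared by both models.
#' @return List of class \code{"delong_comparison"}: \code{auroc_a},
#'   \code{auroc_b}, \code{z}, \code{p}.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("paired comparison needs equal-length score and label vectors")
  }
  labels <- check_two_classes(labels)
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  z <- if (var_diff <= 0) {
    if (abs(d) < 1e-15) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  structure(list(auroc_a = pa$auc, auroc_b = pb$auc, z = z,
                 p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))),
            class = "delong_comparison")
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome; lower is better, 0.25 is the score of a coin-flip forecast.
#'
#' @param probs Predicted probabilities in [0, 1].
#' @param labels Binary outcomes.
#' @export
brier <- function(probs, labels) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (length(probs) != length(labels)) stop("length mismatch")
  mean((probs - as.numeric(labels))^2)
}

#' Bootstrap internal validation
#'
#' Draws \code{B} with-replacement resamples of the rows of \code{data},
#' refits/applies the model on each via \code{model} and records AUROC and
#' Brier.  Resamples containing a single outcome class are redrawn (and
#' counted) so B is fixed and the run is reproducible under the seed.
#'
#' @param data Data frame with one row per patient.
#' @param outcome Name of the binary outcome column.
#' @param model Function(train_data) returning a prediction function
#'   \code{function(newdata) -> probabilities}; for a fixed rule, ignore the
#'   training data and return the rule itself.
#' @param B Number of resamples (default 1000).
#' @param seed Integer RNG seed (mandatory).
#' @param eval_on Either "resample" (evaluate each refit on its own resample,
#'   the plain bootstrap distribution; default) or "original" (evaluate each
#'   refit on the full original data).
#' @return List with components \code{auroc} and \code{brier}, each holding
#'   mean, sd, and percentile 2.5/97.5 interval; plus \code{apparent}
#'   (AUROC and Brier of the model fit on and applied to the full data),
#'   \code{optimism} (bootstrap mean minus apparent AUROC), \code{B} and
#'   \code{redraws}.
#' @export
bootstrap_validate <- function(data, outcome, model, B = 1000, seed,
                               eval_on = c("resample", "original")) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  eval_on <- match.arg(eval_on)
  if (B < 1) stop("B must be >= 1")
  y_full <- as.logical(data[[outcome]])
  check_two_classes(y_full)
  pred_full <- model(data)(data)
  apparent <- c(auroc = auroc_mann_whitney(pred_full, y_full),
                brier = brier(pmin(pmax(pred_full, 0), 1), y_full))
  set.seed(seed)
  n <- nrow(data)
  aucs <- briers <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y_full[idx])) == 2) break
      redraws <- redraws + 1L
    }
    boot <- data[idx, , drop = FALSE]
    fitted <- model(boot)
    target <- if (eval_on == "resample") boot else data
    ytgt <- if (eval_on == "resample") y_full[idx] else y_full
    pr <- fitted(target)
    aucs[b] <- auroc_mann_whitney(pr, ytgt)
    briers[b] <- brier(pmin(pmax(pr, 0), 1), ytgt)
  }
  summ <- function(x) {
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    list(mean = mean(x), sd = stats::sd(x), ci = c(lo = q[1], hi = q[2]))
  }
  list(auroc = summ(aucs), brier = summ(briers), apparent = apparent,
       optimism = mean(aucs) - apparent[["auroc"]], B = B, redraws = redraws)
}
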