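#' Confusion counts with abstentions
#'
#' Tallies true/false positives/negatives over the compounds that received a
#' prediction; abstaining compounds (prediction `NA` or `"no-prediction"`)
#' are excluded from the counts but remain in `n_total`, so the prediction
#' rate can be reported alongside the accuracy-type indicators.
#'
#' @param y_true Character vector of `"active"`/`"inactive"`.
#' @param y_pred Character vector of `"active"`/`"inactive"`, with `NA` or
#'   `"no-prediction"` marking abstention.
#' @param n_total Total number of compounds offered; defaults to
#'   `length(y_true)`.
#' @return A `confusion_counts` list: TP, TN, FP, FN, n_total.
#' @export
#' @examples
#' confusion(c("active", "inactive"), c("active", "active"))
confusion <- function(y_true, y_pred, n_total = length(y_true)) {
  stopifnot(length(y_true) == length(y_pred))
  y_pred[y_pred %in% "no-prediction"] <- NA_character_
  ok <- c("active", "inactive")
  if (!all(y_true %in% ok)) abort("y_true labels must be active/inactive")
  if (!all(y_pred %in% ok | is.na(y_pred))) {
    abort("y_pred labels must be active/inactive/abstain")
  }
  keep <- !is.na(y_pred)
  t <- y_true[keep]; p <- y_pred[keep]
  structure(
    list(
      TP = sum(t == "active" & p == "active"),
      TN = sum(t == "inactive" & p == "inactive"),
      FP = sum(t == "inactive" & p == "active"),
      FN = sum(t == "active" & p == "inactive"),
      n_total = as.integer(n_total)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$TP, " TN=", x$TN, " FP=", x$FP,
      " FN=", x$FN, " of ", x$n_total, "\n", sep = "")
  invisible(x)
}

#' Classification quality indicators
#'
#' Computes the standard confusion-matrix indicators: sensitivity
#' SE = TP/(TP+FN), specificity SP = TN/(TN+FP), negative and positive
#' predictive values, Matthews correlation coefficient, prediction rate
#' PR = predicted/total, and two accuracies — `acc_standard` =
#' (TP+TN)/(TP+TN+FP+FN) and `acc_balanced` = (SP+SE)/2. Both accuracies are
#' always reported; they coincide only for balanced predictions. Any
#' indicator with a zero denominator is returned as `NA` (flagged
#' undefined), except MCC which uses the common zero-denominator-means-zero
#' convention.
#'
#' @param cc A `confusion_counts`, or anything coercible via [confusion()]
#'   arguments passed in `...`.
#' @param ... Passed to [confusion()] when `cc` is not already counts.
#' @return One-row tibble with TP, TN, FP, FN, n_predicted, n_total, PR, SE,
#'   SP, acc_standard, acc_balanced, NPV, PPV, MCC.
#' @export
#' @examples
#' quality_indicators(confusion_from_counts(TP = 44, TN = 61, FP = 9, FN = 6,
#'                                          n_total = 120))
quality_indicators <- function(cc, ...) {
  if (!inherits(cc, "confusion_counts")) cc <- confusion(cc, ...)
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n_pred <- TP + TN + FP + FN
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- safe_div(TP, TP + FN)
  sp <- safe_div(TN, TN + FP)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  if (n_pred == 0) mcc <- NA_real_
  tibble::tibble(
    TP = TP, TN = TN, FP = FP, FN = FN,
    n_predicted = n_pred, n_total = cc$n_total,
    PR = safe_div(n_pred, cc$n_total),
    SE = se, SP = sp,
    acc_standard = safe_div(TP + TN, n_pred),
    acc_balanced = if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2,
    NPV = safe_div(TN, TN + FN),
    PPV = safe_div(TP, TP + FP),
    MCC = mcc
  )
}

#' Build confusion counts directly from tallies
#'
#' Convenience for working from published confusion tables.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @param n_total Total compounds offered; defaults to the tally sum.
#' @return A `confusion_counts`.
#' @export
confusion_from_counts <- function(TP, TN, FP, FN,
                                  n_total = TP + TN + FP + FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    abort("counts must be non-negative integers")
  }
  if (TP + TN + FP + FN > n_total) abort("counts exceed n_total")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 n_total = as.integer(n_total)),
            class = "confusion_counts")
}

#' ROC curve and AUC
#'
#' Standard staircase swept over all score thresholds (higher score = more
#' active), with AUC by the trapezoid rule.
#'
#' @param scores Numeric prediction scores.
#' @param y_true Labels `"active"`/`"inactive"`; both classes must occur.
#' @return A `qsar_roc`: list with `points` (tibble of threshold, TPR, FPR)
#'   and `auc`.
#' @export
#' @examples
#' roc_curve(c(.9, .8, .3, .1), c("active", "inactive", "active", "inactive"))$auc
roc_curve <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true))
  pos <- y_true == "active"
  if (!any(pos) || all(pos)) abort("need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tied block
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(
      points = tibble::tibble(threshold = c(Inf, s[last]),
                              TPR = tpr, FPR = fpr),
      auc = auc,
      n_active = sum(pos), n_inactive = sum(!pos)
    ),
    class = "qsar_roc"
  )
}

#' @export
print.qsar_roc <- function(x, ...) {
  cat("<qsar_roc> AUC = ", signif(x$auc, 4), " (", x$n_active,
      " active / ", x$n_inactive, " inactive)\n", sep = "")
  invisible(x)
}

#' External validation metrics for regression models
#'
#' Computes the regression validation suite against an external set:
#' \itemize{
#'   \item `R2` — squared Pearson correlation of observed vs predicted;
#'   \item `RMSE` — root mean squared error (pKi units);
#'   \item `Q2_F3` — \eqn{1 - [\sum(obs-pred)^2/n_{ext}] /
#'     [\sum(y_{tr}-\bar y_{tr})^2/n_{tr}]}, referencing the training
#'     variance so the statistic is comparable across external sets;
#'   \item `CCC` — Lin's concordance correlation,
#'     \eqn{2\,cov / (var_{obs} + var_{pred} + (\bar{obs}-\bar{pred})^2)}
#'     (population moments), penalizing location and scale bias;
#'   \item `rm2` — \eqn{R^2 (1 - \sqrt{R^2 - R_0^2})} with \eqn{R_0^2} the
#'     through-origin coefficient of determination of observed on predicted.
#' }
#'
#' @param y_obs,y_pred Observed and predicted values for the external set.
#' @param y_train Observed training values (for the Q2_F3 reference
#'   variance).
#' @return One-row tibble with R2, RMSE, Q2_F3, CCC, r0_2, rm2. Metrics
#'   undefined through zero variance are `NA`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2), y_train = c(0, 1, 2, 3))
regression_metrics <- function(y_obs, y_pred, y_train) {
  stopifnot(length(y_obs) == length(y_pred), length(y_train) > 0)
  n <- length(y_obs)
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  tr_var <- sum((y_train - mean(y_train))^2) / length(y_train)
  q2f3 <- if (tr_var == 0) NA_real_ else 1 - mean((y_obs - y_pred)^2) / tr_var

  degenerate <- var(y_obs) == 0 || var(y_pred) == 0
  if (degenerate) {
    r2 <- NA_real_; ccc <- NA_real_; r0 <- NA_real_; rm2 <- NA_real_
  } else {
    r2 <- cor(y_obs, y_pred)^2
    mo <- mean(y_obs); mp <- mean(y_pred)
    cov_p <- mean((y_obs - mo) * (y_pred - mp))
    var_o <- mean((y_obs - mo)^2)
    var_p <- mean((y_pred - mp)^2)
    ccc <- 2 * cov_p / (var_o + var_p + (mo - mp)^2)
    k0 <- sum(y_obs * y_pred) / sum(y_pred^2)
    r0 <- 1 - sum((y_obs - k0 * y_pred)^2) / sum((y_obs - mo)^2)
    rm2 <- r2 * (1 - sqrt(max(0, r2 - r0)))
  }
  tibble::tibble(R2 = r2, RMSE = rmse, Q2_F3 = q2f3, CCC = ccc,
                 r0_2 = r0, rm2 = rm2, n_ext = n)
}
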