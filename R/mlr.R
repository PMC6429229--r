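#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares on an intercept-augmented design. The fitted
#' object stores the inverse Gram matrix of the training design so that
#' leverages of new compounds can be computed, and the leverage warning
#' threshold `hat_star = 3 (p + 1) / n` (p descriptors, n training
#' compounds) used as the applicability domain: for 11 descriptors and 90
#' training compounds this gives exactly 0.4.
#'
#' For classification the same machinery is used on a 0/1 target
#' (active = 1) and predictions are thresholded (see [predict.qsar_mlr()]).
#'
#' @param data Standardized descriptor tibble.
#' @param y Numeric targets, or `"active"`/`"inactive"` labels (encoded 0/1).
#' @param scaling Optional `scaling_params` to embed (defaults to
#'   `attr(data, "scaling")`).
#' @return A `qsar_mlr` model object.
#' @export
#' @examples
#' hat_star(p = 11, n = 90)
fit_mlr <- function(data, y, scaling = NULL) {
  x <- desc_matrix(data)
  n <- nrow(x)
  p <- ncol(x)
  task <- if (is.numeric(y)) "regression" else "classification"
  y_num <- if (task == "classification") {
    if (!all(y %in% c("active", "inactive"))) {
      abort("classification targets must be 'active'/'inactive'")
    }
    as.numeric(y == "active")
  } else as.numeric(y)
  if (length(y_num) != n) abort("`y` must align with descriptor rows")
  if (n <= p + 1L) abort("need more training compounds than descriptors + 1")

  xa <- cbind(`(Intercept)` = 1, x)
  qr_fit <- qr(xa)
  if (qr_fit$rank < ncol(xa)) {
    bad <- colnames(xa)[qr_fit$pivot[seq(qr_fit$rank + 1L, ncol(xa))]]
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qr_fit, y_num)
  gram_inv <- solve(crossprod(xa))
  dimnames(gram_inv) <- list(colnames(xa), colnames(xa))

  fitted <- as.vector(xa %*% coefs)
  structure(
    list(
      coefficients = coefs,
      descriptor_names = colnames(x),
      scaling = scaling %||% attr(data, "scaling"),
      gram_inverse = gram_inv,
      hat_star = hat_star(p, n),
      n_train = n,
      task = task,
      sigma2 = sum((y_num - fitted)^2) / max(1L, n - p - 1L),
      r_squared = if (var(y_num) > 0) {
        1 - sum((y_num - fitted)^2) / sum((y_num - mean(y_num))^2)
      } else NA_real_
    ),
    class = "qsar_mlr"
  )
}

#' Leverage warning threshold
#'
#' `hat_star = 3 (p + 1) / n`, the customary cutoff on hat-matrix diagonals
#' marking compounds structurally distant from the training set.
#'
#' @param p Number of descriptors in the model.
#' @param n Number of training compounds.
#' @return The threshold (scalar).
#' @export
#' @examples
#' hat_star(11, 90) # 0.4
hat_star <- function(p, n) 3 * (p + 1) / n

#' Leverage of compounds under a fitted MLR model
#'
#' `h = x'(X'X)^{-1} x` for the intercept-augmented descriptor vector; the
#' diagonal of the hat matrix for training compounds.
#'
#' @param model A `qsar_mlr` model.
#' @param data Descriptor tibble (scaled like the training data).
#' @return Numeric vector of leverages, named by compound id.
#' @export
leverage <- function(model, data) {
  stopifnot(inherits(model, "qsar_mlr"))
  x <- prepare_newdata(data, model$descriptor_names, model$scaling)
  xa <- cbind(1, x)
  h <- rowSums((xa %*% model$gram_inverse) * xa)
  setNames(h, rownames(x))
}

#' Predict with a fitted MLR model
#'
#' Raw output is the linear prediction. When a classification cut is in
#' force (the model was fitted on labels, or `classification_cut` is
#' given), the label is active iff the raw output is `>=` the cut. The
#' applicability-domain flag is true iff the compound's leverage does not
#' exceed `hat_star` (strict gate: leverage above the threshold fails).
#'
#' @param object A `qsar_mlr` model.
#' @param newdata Descriptor tibble; unscaled input is scaled with the
#'   model's training statistics.
#' @param classification_cut Decision cut on the raw output; defaults to
#'   0.5 for models fitted on labels, absent for regression fits.
#' @param ... Unused.
#' @return Tibble with `compound_id`, `raw_output`, `prediction`,
#'   `leverage`, `ad_flag`.
#' @export
predict.qsar_mlr <- function(object, newdata, classification_cut = NULL, ...) {
  x <- prepare_newdata(newdata, object$descriptor_names, object$scaling)
  xa <- cbind(1, x)
  raw <- as.vector(xa %*% object$coefficients)
  h <- rowSums((xa %*% object$gram_inverse) * xa)
  cut <- classification_cut %||%
    (if (object$task == "classification") 0.5 else NULL)
  out <- tibble::tibble(
    compound_id = rownames(x),
    raw_output = raw,
    leverage = h,
    ad_flag = h <= object$hat_star
  )
  out$prediction <- if (!is.null(cut)) {
    ifelse(raw >= cut, "active", "inactive")
  } else raw
  out[, c("compound_id", "raw_output", "prediction", "leverage", "ad_flag")]
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat("<qsar_mlr> ", x$task, ", ", length(x$descriptor_names),
      " descriptors, n = ", x$n_train, ", hat* = ",
      signif(x$hat_star, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_mlr Coefficient table (term, estimate).
#' @param x A `qsar_mlr` model.
#' @param ... Unused.
#' @method tidy qsar_mlr
#' @export
tidy.qsar_mlr <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn fit_mlr One-row fit summary.
#' @method glance qsar_mlr
#' @export
glance.qsar_mlr <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_descriptors = length(x$descriptor_names),
    n_train = x$n_train,
    r_squared = x$r_squared,
    hat_star = x$hat_star
  )
}
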