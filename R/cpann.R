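#' Configuration for a counter-propagation neural network
#'
#' @param grid_rows,grid_cols Kohonen grid dimensions; default 10 x 10,
#'   conventional for training sets of roughly 90-120 compounds (neuron
#'   count near compound count).
#' @param epochs Training epochs; default 100.
#' @param eta_max,eta_min Learning-rate schedule endpoints in (0, 1]; the
#'   rate decays linearly from `eta_max` to `eta_min` over epochs.
#' @param neighborhood Only `"triangular"` is implemented: the update weight
#'   falls off linearly with grid distance from the winner and the radius
#'   shrinks from the full grid to winner-only.
#' @param toroidal Must be `FALSE`; the map is planar.
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch presentation order.
#' @return A `cpann_config` list.
#' @export
cpann_config <- function(grid_rows = 10L, grid_cols = 10L, epochs = 100L,
                         eta_max = 0.5, eta_min = 0.01,
                         neighborhood = "triangular", toroidal = FALSE,
                         seed = 1L) {
  if (eta_max < eta_min || eta_min <= 0 || eta_max > 1) {
    abort("need eta_max >= eta_min > 0 and eta_max <= 1")
  }
  if (!identical(neighborhood, "triangular")) {
    abort("only the triangular neighborhood is implemented")
  }
  if (isTRUE(toroidal)) abort("toroidal maps are not implemented")
  structure(
    list(
      grid_rows = check_count(grid_rows, "grid_rows"),
      grid_cols = check_count(grid_cols, "grid_cols"),
      epochs = check_count(epochs, "epochs"),
      eta_max = eta_max, eta_min = eta_min,
      neighborhood = neighborhood, toroidal = FALSE,
      seed = as.integer(seed)
    ),
    class = "cpann_config"
  )
}

#' Train a counter-propagation neural network
#'
#' A Kohonen self-organizing map augmented with an output layer. Each
#' training vector selects its winning neuron by Euclidean distance in the
#' Kohonen layer; the Kohonen weights of the neighbourhood move toward the
#' input and, counter-propagated, the output weights of the same neurons
#' move toward the target. For classification the target is encoded 0/1
#' (active = 1) on a single output channel; for regression it is pKi.
#'
#' The applicability domain is recorded as `ed_crt`, the maximal Euclidean
#' distance of any training compound to its winning neuron on the final map;
#' predictions farther from their winner than `ed_crt` are flagged
#' out-of-domain.
#'
#' @param data Standardized descriptor tibble (see [autoscale()]).
#' @param y Targets aligned with `data` rows: a character/factor vector of
#'   `"active"`/`"inactive"` (classification) or a numeric vector
#'   (regression).
#' @param config A [cpann_config()].
#' @param scaling Optional `scaling_params` to embed in the model (taken
#'   from `attr(data, "scaling")` when present).
#' @param history_blocks Number of equally spaced epochs at which training
#'   RMSE is recorded; default 10.
#' @return A `cpann` model object.
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 1))
#' xs <- autoscale(d$descriptors)
#' m <- train_cpann(xs, d$activities$class,
#'                  cpann_config(grid_rows = 6, grid_cols = 6, epochs = 30))
#' glance(m)
train_cpann <- function(data, y, config = cpann_config(), scaling = NULL,
                        history_blocks = 10L) {
  x <- desc_matrix(data)
  if (nrow(x) == 0L) abort("empty training set")
  if (any(!is.finite(x))) abort("non-finite descriptor values")
  if (length(y) != nrow(x)) abort("`y` must align with descriptor rows")
  scaling <- scaling %||% attr(data, "scaling")

  task <- if (is.numeric(y)) "regression" else "classification"
  y_num <- if (task == "classification") {
    if (!all(y %in% c("active", "inactive"))) {
      abort("classification targets must be 'active'/'inactive'")
    }
    as.numeric(y == "active")
  } else {
    if (any(!is.finite(y))) abort("non-finite regression targets")
    as.numeric(y)
  }

  fit <- with_seed(config$seed, {
    train_cpann_core(x, y_num, config, history_blocks)
  })

  # AD cutoff: maximal training distance to the winning neuron on the
  # final map.
  d_train <- vapply(seq_len(nrow(x)),
                    function(i) winner_of(fit$w, x[i, ])$distance,
                    numeric(1))
  structure(
    list(
      kohonen_weights = fit$w,
      output_weights = as.vector(fit$u),
      grid_rows = config$grid_rows,
      grid_cols = config$grid_cols,
      descriptor_names = colnames(x),
      scaling = scaling,
      ed_crt = max(d_train),
      task = task,
      config = config,
      rmse_history = fit$history,
      n_train = nrow(x)
    ),
    class = "cpann"
  )
}

# Training loop with periodic training-RMSE snapshots. Assumes the RNG is
# already scoped by the caller.
train_cpann_core <- function(x, y_num, config, history_blocks) {
  rows <- config$grid_rows
  cols <- config$grid_cols
  epochs <- config$epochs
  n <- nrow(x)
  gd <- grid_distances(rows, cols)
  w <- matrix(runif(rows * cols * ncol(x), -0.5, 0.5), rows * cols, ncol(x))
  colnames(w) <- colnames(x)
  u <- matrix(runif(rows * cols, min(y_num), max(y_num)), rows * cols, 1L)

  r_max <- max(rows, cols) - 1L
  at <- unique(pmax(1L, round(seq_len(history_blocks) * epochs / history_blocks)))
  history <- numeric(0)
  for (t in seq_len(epochs)) {
    frac <- if (epochs > 1L) (t - 1) / (epochs - 1) else 1
    eta <- config$eta_max + (config$eta_min - config$eta_max) * frac
    radius <- floor(r_max * (1 - frac))
    for (i in sample.int(n)) {
      xi <- x[i, ]
      win <- winner_of(w, xi)$index
      nb <- which(gd[win, ] <= radius)
      a <- eta * (1 - gd[win, nb] / (radius + 1))
      w[nb, ] <- w[nb, ] + a * (rep(xi, each = length(nb)) - w[nb, , drop = FALSE])
      u[nb, ] <- u[nb, ] + a * (y_num[i] - u[nb, , drop = FALSE])
    }
    if (t %in% at) {
      pred <- vapply(seq_len(n),
                     function(i) u[winner_of(w, x[i, ])$index, 1L],
                     numeric(1))
      history <- c(history, sqrt(mean((y_num - pred)^2)))
    }
  }
  list(w = w, u = u, history = setNames(history, at))
}

#' Locate the winning neuron for a descriptor vector
#'
#' @param model A `cpann` model.
#' @param x Numeric vector in the model's descriptor space (already scaled
#'   with the model's training statistics).
#' @return List with `neuron` (row-major index, ties to the lowest index)
#'   and `distance` (Euclidean).
#' @export
find_winner <- function(model, x) {
  stopifnot(inherits(model, "cpann"))
  if (length(x) != length(model$descriptor_names)) {
    abort("descriptor dimension mismatch")
  }
  win <- winner_of(model$kohonen_weights, as.numeric(x))
  list(neuron = win$index, distance = win$distance)
}

#' Predict with a counter-propagation network
#'
#' Each compound is assigned its winning neuron's output weight. For
#' classification the label is active iff the raw output is `>= 0.5`
#' (boundary assigned to active); for regression the raw output is the
#' predicted pKi. The applicability-domain flag is true iff the winner
#' distance does not exceed the model's `ed_crt`.
#'
#' @param object A `cpann` model.
#' @param newdata Descriptor tibble. If unscaled (no `"scaling"` attribute)
#'   and the model carries scaling parameters, the training scaling is
#'   applied automatically; descriptor names must match the model's.
#' @param ... Unused.
#' @return Tibble with `compound_id`, `raw_output`, `prediction` (label or
#'   pKi), `distance`, `ad_flag`.
#' @export
predict.cpann <- function(object, newdata, ...) {
  x <- prepare_newdata(newdata, object$descriptor_names, object$scaling)
  hits <- t(vapply(seq_len(nrow(x)), function(i) {
    win <- winner_of(object$kohonen_weights, x[i, ])
    c(win$index, win$distance)
  }, numeric(2)))
  raw <- object$output_weights[hits[, 1L]]
  out <- tibble::tibble(
    compound_id = rownames(x),
    raw_output = raw,
    distance = hits[, 2L],
    ad_flag = hits[, 2L] <= object$ed_crt
  )
  if (object$task == "classification") {
    out$prediction <- ifelse(raw >= 0.5, "active", "inactive")
  } else {
    out$prediction <- raw
  }
  out[, c("compound_id", "raw_output", "prediction", "distance", "ad_flag")]
}

# Align, and if necessary scale, new descriptor data for a model.
prepare_newdata <- function(newdata, descriptor_names, scaling) {
  x <- desc_matrix(newdata)
  missing <- setdiff(descriptor_names, colnames(x))
  if (length(missing)) {
    abort(paste0("missing descriptors: ", paste(missing, collapse = ", ")))
  }
  already_scaled <- !is.null(attr(newdata, "scaling")) ||
    length(descriptor_names) == 0L
  if (!already_scaled) {
    if (is.null(scaling)) {
      abort("newdata is unscaled and the model carries no scaling parameters")
    }
    x <- sweep(sweep(x, 2, scaling$mean[colnames(x)]), 2,
               scaling$sd[colnames(x)], "/")
  }
  x[, descriptor_names, drop = FALSE]
}

#' @export
print.cpann <- function(x, ...) {
  cat("<cpann> ", x$task, " map ", x$grid_rows, "x", x$grid_cols,
      ", ", length(x$descriptor_names), " descriptors, ",
      x$config$epochs, " epochs, ED_crt = ", signif(x$ed_crt, 4),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn train_cpann Per-neuron tibble: grid position, output weight,
#'   and training occupancy is not stored — weights only.
#' @param x A `cpann` model.
#' @param ... Unused.
#' @method tidy cpann
#' @export
tidy.cpann <- function(x, ...) {
  tibble::tibble(
    neuron = seq_len(x$grid_rows * x$grid_cols),
    row = rep(seq_len(x$grid_rows), each = x$grid_cols),
    col = rep(seq_len(x$grid_cols), times = x$grid_rows),
    output_weight = x$output_weights
  )
}

#' @describeIn train_cpann One-row model summary.
#' @method glance cpann
#' @export
glance.cpann <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    grid = paste0(x$grid_rows, "x", x$grid_cols),
    n_descriptors = length(x$descriptor_names),
    n_train = x$n_train,
    epochs = x$config$epochs,
    ed_crt = x$ed_crt,
    final_train_rmse = unname(tail(x$rmse_history, 1L))
  )
}
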