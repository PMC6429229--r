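#' Autoscale descriptors to zero mean and unit standard deviation
#'
#' Centres and scales each descriptor column. When `params` is absent the
#' scaling is fitted on `data` (a training partition) using the population
#' standard deviation (denominator n); when `params` is supplied it is
#' applied as-is, so test and screening compounds are always expressed in
#' training-set units.
#'
#' @param data Descriptor tibble (first column `compound_id`).
#' @param params Optional `scaling_params` from a previous fit.
#' @return The scaled tibble, with the `scaling_params` attached as attribute
#'   `"scaling"` (retrieve with [get_scaling()]).
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 1))
#' s <- autoscale(d$descriptors)
#' colMeans(desc_stats(s))
autoscale <- function(data, params = NULL) {
  x <- desc_matrix(data)
  if (is.null(params)) {
    mu <- colMeans(x)
    n <- nrow(x)
    sdev <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population sd
    if (any(sdev <= 1e-12)) {
      abort(paste0(
        "zero-variance descriptor(s) encountered while fitting scaling: ",
        paste(colnames(x)[sdev <= 1e-12], collapse = ", "),
        "; run drop_zero_variance() first"
      ))
    }
    params <- structure(
      list(mean = mu, sd = sdev, sd_convention = "population"),
      class = "scaling_params"
    )
  } else {
    stopifnot(inherits(params, "scaling_params"))
    missing <- setdiff(colnames(x), names(params$mean))
    if (length(missing)) {
      abort(paste0("scaling params lack descriptors: ",
                   paste(missing, collapse = ", ")))
    }
  }
  scaled <- sweep(sweep(x, 2, params$mean[colnames(x)]), 2,
                  params$sd[colnames(x)], "/")
  out <- desc_tbl(scaled)
  attr(out, "scaling") <- params
  out
}

#' Retrieve the scaling parameters attached by [autoscale()]
#' @param data A tibble returned by [autoscale()].
#' @return A `scaling_params` object.
#' @export
get_scaling <- function(data) {
  p <- attr(data, "scaling")
  if (is.null(p)) abort("no scaling attached; was this produced by autoscale()?")
  p
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("<scaling_params> ", length(x$mean), " descriptors, ",
      x$sd_convention, "-sd convention\n", sep = "")
  invisible(x)
}

#' Remove descriptors with (near-)zero variance
#'
#' @param data Descriptor tibble.
#' @param tol Variance tolerance; columns with population variance below it
#'   are dropped. Default 1e-12.
#' @return The filtered tibble, survivor order preserved.
#' @export
drop_zero_variance <- function(data, tol = 1e-12) {
  x <- desc_matrix(data)
  v <- colMeans(sweep(x, 2, colMeans(x))^2)
  keep <- v >= tol
  if (!any(keep)) abort("all descriptors have zero variance")
  desc_tbl(x[, keep, drop = FALSE])
}

#' Remove highly intercorrelated descriptors
#'
#' Greedy scan in column order: whenever a pair exceeds the absolute Pearson
#' correlation threshold, the later column is dropped, so the earlier column
#' in the input ordering always survives. Survivors are guaranteed pairwise
#' |r| <= threshold.
#'
#' @param data Descriptor tibble with at least 2 descriptor columns.
#' @param threshold Absolute correlation above which the later column is
#'   dropped; default 0.9.
#' @return The filtered tibble.
#' @export
drop_intercorrelated <- function(data, threshold = 0.9) {
  x <- desc_matrix(data)
  if (ncol(x) < 2L) abort("need at least 2 descriptor columns")
  r <- abs(stats::cor(x))
  p <- ncol(x)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(p) > j)
    drop <- later[r[j, later] > threshold]
    keep[drop] <- FALSE
  }
  desc_tbl(x[, keep, drop = FALSE])
}

#' Label activity by a strict pKi threshold
#'
#' Active means pKi strictly greater than the threshold; a compound exactly
#' at the threshold is inactive.
#'
#' @param pKi Numeric vector of pKi values (\eqn{-\log_{10} K_i}, Ki in
#'   mmol/L).
#' @param threshold Activity cut, default 1.3.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
#' @examples
#' classify_by_threshold(c(1.31, 1.3, -0.5))
classify_by_threshold <- function(pKi, threshold = 1.3) {
  if (any(!is.finite(pKi))) abort("pKi must be finite and non-missing")
  ifelse(pKi > threshold, "active", "inactive")
}

#' Split compounds into training / (test) / validation partitions
#'
#' Two methods are offered. `"random"` splits at random, stratified by
#' activity class so both classes appear in every partition in proportion.
#' `"som"` trains a self-organizing map on the descriptors and draws
#' held-out compounds per occupied neuron proportionally, taking from each
#' sampled neuron the compound farthest from the neuron's weight vector —
#' a deterministic, coverage-preserving rule that keeps the training set
#' spread over the occupied map.
#'
#' @param data Descriptor tibble.
#' @param activities Activity tibble with `compound_id` and `class`.
#' @param fractions Two or three fractions summing to 1, e.g. `c(.75, .25)`
#'   for train/validation or `c(.60, .25, .15)` for train/test/validation.
#' @param method `"random"` or `"som"`.
#' @param seed Integer seed.
#' @param grid SOM grid (rows, cols) for method `"som"`; default `c(6, 6)`.
#' @return A `dataset_split`: list of `train_ids`, optional `test_ids`,
#'   `validation_ids`, plus the fractions and method used.
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 1))
#' sp <- split_dataset(d$descriptors, d$activities, c(.75, .25), seed = 2)
#' lengths(sp[c("train_ids", "validation_ids")])
split_dataset <- function(data, activities, fractions = c(0.75, 0.25),
                          method = c("random", "som"), seed = 1L,
                          grid = c(6L, 6L)) {
  method <- match.arg(method)
  x <- desc_matrix(data)
  if (!length(fractions) %in% 2:3) abort("supply two or three fractions")
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  ids <- rownames(x)
  stopifnot(setequal(ids, activities$compound_id))
  cls <- setNames(activities$class, activities$compound_id)[ids]
  n <- length(ids)

  sizes <- round(n * fractions)
  sizes[1L] <- n - sum(sizes[-1L]) # training absorbs the rounding residual
  held_sizes <- sizes[-1L]

  held <- with_seed(seed, {
    if (method == "random") {
      split_random_stratified(ids, cls, held_sizes)
    } else {
      split_som_coverage(x, held_sizes, grid)
    }
  })
  train <- setdiff(ids, unlist(held))
  if (length(unique(cls[train])) < length(unique(cls))) {
    abort("a class is absent from the training partition; adjust fractions/seed")
  }
  out <- list(train_ids = train)
  if (length(held) == 2L) {
    out$test_ids <- held[[1L]]
    out$validation_ids <- held[[2L]]
  } else {
    out$validation_ids <- held[[1L]]
  }
  out$fractions <- fractions
  out$method <- method
  out$seed <- as.integer(seed)
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  sizes <- vapply(x[intersect(names(x), c("train_ids", "test_ids",
                                          "validation_ids"))],
                  length, integer(1))
  cat("<dataset_split> ", paste(names(sizes), sizes, sep = "=",
                                collapse = ", "),
      " (", x$method, ")\n", sep = "")
  invisible(x)
}

# Stratified random held-out draw: each held-out partition receives the
# per-class rounded share; residuals assigned from the largest class.
split_random_stratified <- function(ids, cls, held_sizes) {
  pool <- split(ids, cls)
  pool <- lapply(pool, sample_vec) # seeded shuffle within class
  held <- vector("list", length(held_sizes))
  for (k in seq_along(held_sizes)) {
    want <- held_sizes[k]
    avail <- lengths(pool)
    take <- round(want * avail / sum(avail))
    while (sum(take) < want) {
      i <- which.max(avail - take)
      take[i] <- take[i] + 1L
    }
    while (sum(take) > want) {
      i <- which.max(take)
      take[i] <- take[i] - 1L
    }
    sel <- unlist(purrr::map2(pool, take, ~ head(.x, .y)), use.names = FALSE)
    pool <- purrr::map2(pool, take, ~ if (.y > 0) .x[-seq_len(.y)] else .x)
    held[[k]] <- sel
  }
  held
}

# Coverage-preserving SOM draw: map compounds onto a trained map, then cycle
# over occupied neurons (largest first), holding out the compound farthest
# from the neuron weight vector at each visit.
split_som_coverage <- function(x, held_sizes, grid) {
  som <- som_fit(x, grid[1L], grid[2L], epochs = 30L)
  mapped <- som_map(som, x)
  held <- vector("list", length(held_sizes))
  remaining <- rownames(x)
  for (k in seq_along(held_sizes)) {
    sel <- character(0)
    while (length(sel) < held_sizes[k]) {
      occ <- mapped[mapped$compound_id %in% setdiff(remaining, sel), ]
      counts <- sort(table(occ$neuron), decreasing = TRUE)
      for (nr in names(counts)) {
        if (length(sel) >= held_sizes[k]) break
        cand <- occ[occ$neuron == as.integer(nr), ]
        # farthest compound from the neuron centroid leaves first
        sel <- c(sel, cand$compound_id[which.max(cand$distance)])
        occ <- occ[!occ$compound_id %in% sel, ]
      }
    }
    held[[k]] <- sel
    remaining <- setdiff(remaining, sel)
  }
  held
}
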