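#' Configuration for genetic-algorithm descriptor selection
#'
#' @param population_size Chromosomes per generation; default 24.
#' @param generations Number of generations; 0 returns the best of the
#'   random initial population.
#' @param crossover_rate,mutation_rate Probabilities of uniform crossover
#'   per pair and bit-flip per position.
#' @param elitism Number of top chromosomes copied unchanged; must be
#'   smaller than the population.
#' @param subset_min,subset_max Bounds on selected-subset size; offspring
#'   outside the bounds are repaired by random add/remove.
#' @param cv_folds Cross-validation folds for the fitness; default 5.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 24L, generations = 15L,
                      crossover_rate = 0.9, mutation_rate = 0.02,
                      elitism = 2L, subset_min = 3L, subset_max = 18L,
                      cv_folds = 5L, seed = 1L) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  population_size <- check_count(population_size, "population_size", min = 2L)
  elitism <- check_count(elitism, "elitism", min = 0L)
  if (elitism >= population_size) abort("`elitism` must be < population_size")
  structure(
    list(
      population_size = population_size,
      generations = check_count(generations, "generations", min = 0L),
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      elitism = elitism,
      subset_min = check_count(subset_min, "subset_min"),
      subset_max = check_count(subset_max, "subset_max"),
      cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
      seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

# k-fold assignment; stratified by label for classification. Retries with a
# seed offset (up to 5 attempts) if some fold lacks a class.
make_folds <- function(y, k, seed, stratified) {
  for (attempt in 0:4) {
    folds <- with_seed(seed + attempt, {
      if (stratified) {
        f <- integer(length(y))
        for (lv in unique(y)) {
          idx <- sample_vec(which(y == lv))
          f[idx] <- rep_len(seq_len(k), length(idx))
        }
        f
      } else {
        sample(rep_len(seq_len(k), length(y)))
      }
    })
    ok <- all(vapply(seq_len(k), function(j) {
      !stratified || length(unique(y[folds != j])) == length(unique(y))
    }, logical(1)))
    if (ok) return(folds)
  }
  abort("could not build folds with every class present in training")
}

#' Cross-validated fitness of a descriptor subset
#'
#' k-fold cross-validation restricted to the masked descriptors; folds are
#' stratified by class for classification. The score is the mean held-out
#' standard accuracy (classification) or the mean held-out R-squared
#' (regression). Scaling is refitted inside each fold on the training part
#' only.
#'
#' @param mask Logical/0-1 vector over the descriptor columns of `data`.
#' @param data Descriptor tibble.
#' @param y Labels (`"active"`/`"inactive"`) or numeric targets.
#' @param model_type `"mlr"` (fast, default) or `"cpann"`.
#' @param folds Number of folds.
#' @param seed Integer seed (fold assignment and CP-ANN training).
#' @param cpann_cfg Optional [cpann_config()] template for
#'   `model_type = "cpann"`; a small fast map is used by default.
#' @return Scalar score.
#' @export
cv_fitness <- function(mask, data, y, model_type = c("mlr", "cpann"),
                       folds = 5L, seed = 1L, cpann_cfg = NULL) {
  model_type <- match.arg(model_type)
  x <- desc_matrix(data)
  mask <- as.logical(mask)
  if (length(mask) != ncol(x)) abort("mask length must equal descriptor count")
  if (!any(mask)) abort("mask selects no descriptors")
  classification <- !is.numeric(y)
  fold_id <- make_folds(y, folds, seed, stratified = classification)
  cols <- which(mask)

  scores <- vapply(seq_len(folds), function(j) {
    tr <- fold_id != j
    xs_tr <- autoscale(desc_tbl(x[tr, cols, drop = FALSE]))
    xs_te <- autoscale(desc_tbl(x[!tr, cols, drop = FALSE]),
                       params = get_scaling(xs_tr))
    if (model_type == "mlr") {
      fit <- fit_mlr(xs_tr, y[tr])
      pred <- predict(fit, xs_te)
    } else {
      cfg <- cpann_cfg %||%
        cpann_config(grid_rows = 6L, grid_cols = 6L, epochs = 30L,
                     seed = seed + j)
      fit <- train_cpann(xs_tr, y[tr], cfg)
      pred <- predict(fit, xs_te)
    }
    if (classification) {
      mean(pred$prediction == y[!tr])
    } else {
      obs <- y[!tr]
      if (var(obs) == 0) return(NA_real_)
      cor(obs, as.numeric(pred$prediction))^2
    }
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Genetic-algorithm descriptor selection
#'
#' Binary-mask GA with tournament selection (size 2), uniform crossover,
#' per-bit mutation, repair of subset sizes to `[subset_min, subset_max]`
#' (random add/remove) and elitism, maximizing [cv_fitness()]. Elitism makes
#' the best-ever fitness non-decreasing across generations.
#'
#' @param data Descriptor tibble (the candidate pool).
#' @param y Targets (labels or numeric).
#' @param model_type `"mlr"` or `"cpann"` fitness model.
#' @param config A [ga_config()].
#' @param cpann_cfg Passed to [cv_fitness()].
#' @return A `ga_result`: `best_mask` (named logical), `best_fitness`,
#'   `fitness_history` tibble, `evaluated_count`, `config`.
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(n_descriptors = 12, seed = 1))
#' res <- ga_search(d$descriptors, d$activities$class,
#'                  config = ga_config(population_size = 8, generations = 2,
#'                                     subset_max = 6, cv_folds = 3))
#' names(which(res$best_mask))
ga_search <- function(data, y, model_type = c("mlr", "cpann"),
                      config = ga_config(), cpann_cfg = NULL) {
  model_type <- match.arg(model_type)
  x <- desc_matrix(data)
  p <- ncol(x)
  cfg <- config
  if (cfg$subset_min > p) abort("subset_min exceeds the descriptor pool")
  smax <- min(cfg$subset_max, p)
  if (cfg$subset_min > smax) abort("infeasible subset size bounds")

  evaluated <- 0L
  score_of <- function(mask) {
    evaluated <<- evaluated + 1L
    cv_fitness(mask, data, y, model_type,
               folds = cfg$cv_folds, seed = cfg$seed, cpann_cfg = cpann_cfg)
  }
  repair <- function(mask) {
    k <- sum(mask)
    if (k < cfg$subset_min) {
      mask[sample_vec(which(!mask), cfg$subset_min - k)] <- TRUE
    } else if (k > smax) {
      mask[sample_vec(which(mask), k - smax)] <- FALSE
    }
    mask
  }

  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population_size), function(i) {
      k <- sample_vec(cfg$subset_min:smax, 1L)
      mask <- rep(FALSE, p)
      mask[sample.int(p, k)] <- TRUE
      mask
    })
    fit <- vapply(pop, score_of, numeric(1))
    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    history <- tibble::tibble(generation = 0L, best = best_fit,
                              mean = mean(fit))

    for (g in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[head(ord, cfg$elitism)]
      children <- list()
      while (length(children) < cfg$population_size - cfg$elitism) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, 2L)
          pop[[cand[which.max(fit[cand])]]]
        }
        pa <- pick(); pb <- pick()
        if (runif(1) < cfg$crossover_rate) {
          swap <- runif(p) < 0.5
          ca <- ifelse(swap, pb, pa)
          cb <- ifelse(swap, pa, pb)
        } else {
          ca <- pa; cb <- pb
        }
        for (child in list(ca, cb)) {
          flip <- runif(p) < cfg$mutation_rate
          child <- xor(child, flip)
          child <- repair(child)
          children[[length(children) + 1L]] <- child
        }
      }
      children <- head(children, cfg$population_size - cfg$elitism)
      pop <- c(elite, children)
      fit <- vapply(pop, score_of, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_mask <- pop[[which.max(fit)]]
      }
      history <- dplyr::bind_rows(
        history,
        tibble::tibble(generation = g, best = best_fit, mean = mean(fit))
      )
    }

    structure(
      list(
        best_mask = setNames(best_mask, colnames(x)),
        best_fitness = best_fit,
        fitness_history = history,
        evaluated_count = evaluated,
        model_type = model_type,
        config = cfg
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> ", sum(x$best_mask), " descriptors selected of ",
      length(x$best_mask), "; fitness ", signif(x$best_fitness, 4),
      " (", x$model_type, ", ", x$evaluated_count, " evaluations)\n",
      sep = "")
  invisible(x)
}

#' @describeIn ga_search Fitness trajectory per generation.
#' @param x A `ga_result`.
#' @param ... Unused.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$fitness_history

#' @describeIn ga_search One-row summary.
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    n_selected = sum(x$best_mask),
    best_fitness = x$best_fitness,
    generations = max(x$fitness_history$generation),
    evaluated = x$evaluated_count
  )
}
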