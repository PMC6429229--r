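#' Configuration for the end-to-end modelling pipeline
#'
#' Controls preprocessing, splitting, GA selection, and the three
#' classification roles plus four regression models that
#' [run_modeling_pipeline()] trains. The roles mirror a common QSAR battery
#' design: one counter-propagation network on the full reduced descriptor
#' pool with a three-way split (`nnc`), one on a GA-reduced descriptor
#' subset (`nnd`), and one MLR classifier on a smaller GA-reduced subset
#' (`qd`); regression networks `M1`-`M4` are trained on active compounds
#' only. Subset-size bounds default to 10 and 11 descriptors — the
#' classical 18/11 reduced-model sizes scaled to the synthetic generator's
#' smaller descriptor pool — and are ordinary config fields.
#'
#' @param corr_threshold Intercorrelation filter cut; default 0.9.
#' @param reduce_grid SOM grid `(rows, cols)` for the Kohonen similarity
#'   reduction. Default `NULL`: a near-square grid with about twice as many
#'   neurons as descriptors, so the reduction condenses only genuinely
#'   similar columns (the correlation filter has already removed the
#'   near-duplicates). Use a smaller grid to force a harder reduction of
#'   redundant descriptor families.
#' @param split_fractions Master train/validation fractions; default
#'   `c(.75, .25)`. The `nnc` role re-splits its training portion 80/20
#'   into train/test, giving the classical 60/25/15 overall shape while
#'   all models share one untouched validation set.
#' @param split_method `"random"` (stratified) or `"som"`.
#' @param ga_classif,ga_qd,ga_regression [ga_config()] templates for the
#'   `nnd` subset, the `qd` subset, and the regression subsets (seeds are
#'   re-derived from the pipeline seed).
#' @param cpann Template [cpann_config()] for classification networks.
#' @param cpann_regression Template for the regression networks.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corr_threshold = 0.9,
                            reduce_grid = NULL,
                            split_fractions = c(0.75, 0.25),
                            split_method = "random",
                            ga_classif = ga_config(population_size = 24L,
                                                   generations = 12L,
                                                   subset_min = 4L,
                                                   subset_max = 10L,
                                                   cv_folds = 5L),
                            ga_qd = ga_config(population_size = 24L,
                                              generations = 12L,
                                              subset_min = 4L,
                                              subset_max = 11L,
                                              cv_folds = 5L),
                            ga_regression = ga_config(population_size = 24L,
                                                      generations = 12L,
                                                      subset_min = 3L,
                                                      subset_max = 8L,
                                                      mutation_rate = 0.05,
                                                      cv_folds = 5L),
                            cpann = cpann_config(grid_rows = 10L,
                                                 grid_cols = 10L,
                                                 epochs = 150L,
                                                 eta_max = 0.7),
                            cpann_regression = cpann_config(grid_rows = 9L,
                                                            grid_cols = 9L,
                                                            epochs = 200L,
                                                            eta_max = 0.7)) {
  structure(
    list(corr_threshold = corr_threshold, reduce_grid = reduce_grid,
         split_fractions = split_fractions, split_method = split_method,
         ga_classif = ga_classif, ga_qd = ga_qd,
         ga_regression = ga_regression,
         cpann = cpann, cpann_regression = cpann_regression),
    class = "pipeline_config"
  )
}

reseed_ga <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }
reseed_cpann <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }

#' Train a full classification + regression model battery
#'
#' Runs the complete modelling protocol on a descriptor/activity dataset:
#' zero-variance filter, intercorrelation filter, Kohonen similarity
#' reduction, train/validation splitting, GA descriptor selection,
#' counter-propagation and MLR model training with their applicability
#' domains, regression networks on active compounds only, and a validation
#' report covering single models and all consensus combinations.
#'
#' @param dataset A `qsar_dataset`, or a list with `descriptors` and
#'   `activities` tibbles of the same shape.
#' @param config A [pipeline_config()].
#' @param seed Master integer seed; every stochastic stage derives its seed
#'   from it, so one seed reproduces the whole battery bit for bit.
#' @return A `qsar_battery` with elements `classifiers` (`nnc`, `nnd`,
#'   `qd`), `regressors` (`M1`-`M4`, each with a leverage companion),
#'   `masks`, `descriptor_pool`, `split`, `validation` (classification and
#'   regression reports), `seed`.
#' @export
run_modeling_pipeline <- function(dataset, config = pipeline_config(),
                                  seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)
  descriptors <- dataset$descriptors
  activities <- dataset$activities

  # --- preprocessing: variance filter -> correlation filter -> SOM pool ---
  filtered <- descriptors |>
    drop_zero_variance() |>
    drop_intercorrelated(threshold = config$corr_threshold)
  grid <- config$reduce_grid
  if (is.null(grid)) {
    side <- ceiling(sqrt(2 * (ncol(filtered) - 1L)))
    grid <- c(side, side)
  }
  # the oversized default grid intentionally exceeds the descriptor count
  pool <- suppressWarnings(
    kohonen_reduce(autoscale(filtered), grid = grid, seed = seed + 101L)
  )
  x_pool <- filtered[c("compound_id", pool)]

  # --- master split (shared validation set) ---
  split <- split_dataset(x_pool, activities, config$split_fractions,
                         method = config$split_method, seed = seed + 202L)
  train_ids <- split$train_ids
  valid_ids <- split$validation_ids
  cls <- setNames(activities$class, activities$compound_id)
  pki <- setNames(activities$pKi, activities$compound_id)

  x_of <- function(ids) x_pool[match(ids, x_pool$compound_id), ]

  # nnc role: further 80/20 split of the training portion (overall ~60/15),
  # full descriptor pool
  nnc_split <- split_dataset(x_of(train_ids),
                             activities[match(train_ids, activities$compound_id), ],
                             c(0.8, 0.2), method = config$split_method,
                             seed = seed + 303L)
  nnc_train <- nnc_split$train_ids

  scale_train <- function(ids, cols) {
    autoscale(x_of(ids)[c("compound_id", cols)])
  }

  # --- GA descriptor selection for the reduced roles ---
  ga_nnd <- ga_search(x_of(train_ids), cls[train_ids], model_type = "mlr",
                      config = reseed_ga(config$ga_classif, seed + 404L))
  ga_qd <- ga_search(x_of(train_ids), cls[train_ids], model_type = "mlr",
                     config = reseed_ga(config$ga_qd, seed + 505L))
  nnd_cols <- names(which(ga_nnd$best_mask))
  qd_cols <- names(which(ga_qd$best_mask))

  # --- classification models ---
  xs_nnc <- scale_train(nnc_train, pool)
  nnc <- train_cpann(xs_nnc, cls[nnc_train],
                     reseed_cpann(config$cpann, seed + 606L))
  xs_nnd <- scale_train(train_ids, nnd_cols)
  nnd <- train_cpann(xs_nnd, cls[train_ids],
                     reseed_cpann(config$cpann, seed + 707L))
  xs_qd <- scale_train(train_ids, qd_cols)
  qd <- fit_mlr(xs_qd, cls[train_ids])

  classifiers <- list(nnc = nnc, nnd = nnd, qd = qd)

  # --- regression models on actives only ---
  active_ids <- activities$compound_id[activities$class == "active"]
  act_train <- intersect(train_ids, active_ids)
  act_valid <- intersect(valid_ids, active_ids)
  regressors <- list()
  reg_masks <- list()
  for (k in 1:4) {
    ga_k <- ga_search(x_of(act_train), pki[act_train], model_type = "mlr",
                      config = reseed_ga(config$ga_regression,
                                         seed + 800L + k))
    cols_k <- names(which(ga_k$best_mask))
    xs_k <- scale_train(act_train, cols_k)
    mod_k <- train_cpann(xs_k, pki[act_train],
                         reseed_cpann(config$cpann_regression,
                                      seed + 900L + k))
    # companion OLS fit on the same design provides leverages for the
    # weighted consensus and a Williams-style AD reference
    lev_k <- fit_mlr(xs_k, pki[act_train])
    regressors[[paste0("M", k)]] <- list(model = mod_k,
                                         leverage_model = lev_k)
    reg_masks[[paste0("M", k)]] <- setNames(pool %in% cols_k, pool)
  }

  masks <- c(
    list(nnc = setNames(rep(TRUE, length(pool)), pool),
         nnd = setNames(pool %in% nnd_cols, pool),
         qd = setNames(pool %in% qd_cols, pool)),
    reg_masks
  )

  battery <- structure(
    list(
      classifiers = classifiers,
      regressors = regressors,
      masks = masks,
      descriptor_pool = pool,
      split = split,
      nnc_split = nnc_split,
      activity_threshold = dataset$spec$activity_threshold %||% 1.3,
      seed = seed
    ),
    class = "qsar_battery"
  )
  battery$validation <- validate_battery(battery, x_pool, activities)
  battery
}

# Per-model predictions for a compound table, with AD-based abstention
# labels for consensus input.
classifier_calls <- function(battery, x_pool) {
  preds <- purrr::map(battery$classifiers, function(m) predict(m, x_pool))
  labels <- purrr::map(preds, function(p) {
    ifelse(p$ad_flag, p$prediction, NA_character_)
  })
  list(predictions = preds, abstaining_labels = labels)
}

# Classification + regression validation reports over the full modeling set
# and the held-out validation compounds.
validate_battery <- function(battery, x_pool, activities) {
  cls <- setNames(activities$class, activities$compound_id)
  pki <- setNames(activities$pKi, activities$compound_id)
  ids <- x_pool$compound_id
  n <- length(ids)
  calls <- classifier_calls(battery, x_pool)
  raw_labels <- purrr::map(calls$predictions, function(p) {
    setNames(p$prediction, p$compound_id)[ids]
  })
  ad_labels <- purrr::map(calls$abstaining_labels, function(l) {
    setNames(l, ids)[ids]
  })

  # Table-1-shaped report: single models predict everything (PR = 1);
  # consensus columns abstain with any out-of-domain member.
  single_rows <- purrr::imap(raw_labels, function(lab, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm),
                     quality_indicators(confusion(cls[ids], lab, n)))
  })
  pm <- tibble::tibble(compound_id = ids,
                       nnc = ad_labels$nnc, nnd = ad_labels$nnd,
                       qd = ad_labels$qd)
  pair_rows <- purrr::map(list(c("nnc", "nnd"), c("nnc", "qd"),
                               c("nnd", "qd")), function(pair) {
    v <- consensus_classify(pm[c("compound_id", pair)], mode = "pairwise")
    dplyr::bind_cols(
      tibble::tibble(model = paste(pair, collapse = "+")),
      quality_indicators(confusion(cls[ids], v$combined_label, n))
    )
  })
  v_ab <- consensus_classify(pm, mode = "A+B")
  lab_a <- ifelse(v_ab$agreement_type == "A", v_ab$combined_label,
                  NA_character_)
  lab_b <- ifelse(v_ab$agreement_type == "B", v_ab$combined_label,
                  NA_character_)
  tri_rows <- list(
    dplyr::bind_cols(tibble::tibble(model = "A"),
                     quality_indicators(confusion(cls[ids], lab_a, n))),
    dplyr::bind_cols(tibble::tibble(model = "B"),
                     quality_indicators(confusion(cls[ids], lab_b, n))),
    dplyr::bind_cols(tibble::tibble(model = "A+B"),
                     quality_indicators(confusion(cls[ids],
                                                  v_ab$combined_label, n)))
  )
  classification <- dplyr::bind_rows(c(single_rows, pair_rows, tri_rows))

  # Validation-set accuracies (shared held-out compounds)
  vids <- battery$split$validation_ids
  val_acc <- purrr::map_dbl(raw_labels, function(lab) {
    mean(lab[vids] == cls[vids])
  })
  v_val <- v_ab[match(vids, v_ab$compound_id), ]
  pred_v <- v_val$combined_label != "no-prediction"
  val_acc["A+B"] <- if (any(pred_v)) {
    mean(v_val$combined_label[pred_v] == cls[vids][pred_v])
  } else NA_real_

  # Regression: per-model metrics on held-out actives + consensus, and a
  # recovery check of the leverage-weighted consensus over all actives
  # (the set the regression battery is built for, AD-gated).
  act_all <- names(cls)[cls == "active"]
  act_train <- intersect(battery$split$train_ids, act_all)
  act_valid <- intersect(vids, act_all)
  reg_predictions <- function(ids) {
    xv <- x_pool[match(ids, x_pool$compound_id), ]
    purrr::imap(battery$regressors, function(r, nm) {
      pr <- predict(r$model, xv)
      h <- leverage(r$leverage_model, xv)
      tibble::tibble(compound_id = pr$compound_id, model = nm,
                     prediction = as.numeric(pr$prediction),
                     leverage = unname(h[pr$compound_id]),
                     ad_flag = pr$ad_flag)
    }) |> dplyr::bind_rows()
  }
  regression <- NULL
  regression_recovery <- NULL
  if (length(battery$regressors)) {
    if (length(act_valid) >= 3L) {
      long_v <- reg_predictions(act_valid)
      regression <- purrr::imap(battery$regressors, function(r, nm) {
        pr <- long_v[long_v$model == nm, ]
        dplyr::bind_cols(
          tibble::tibble(model = nm),
          regression_metrics(pki[pr$compound_id], pr$prediction,
                             y_train = pki[act_train])
        )
      }) |> dplyr::bind_rows()
      cons_v <- consensus_regression_battery(long_v)
      keep_v <- !is.na(cons_v$consensus_weighted)
      if (sum(keep_v) >= 3L) {
        regression <- dplyr::bind_rows(
          regression,
          dplyr::bind_cols(
            tibble::tibble(model = "consensus"),
            regression_metrics(pki[cons_v$compound_id[keep_v]],
                               cons_v$consensus_weighted[keep_v],
                               y_train = pki[act_train])
          )
        )
      }
    }
    cons_a <- consensus_regression_battery(reg_predictions(act_all))
    keep_a <- !is.na(cons_a$consensus_weighted)
    if (sum(keep_a) >= 3L) {
      regression_recovery <- tibble::tibble(
        n_actives = length(act_all),
        n_covered = sum(keep_a),
        r_squared = cor(cons_a$consensus_weighted[keep_a],
                        pki[cons_a$compound_id[keep_a]])^2
      )
    }
  }

  list(classification = classification,
       validation_accuracy = val_acc,
       regression = regression,
       regression_recovery = regression_recovery)
}

#' @export
print.qsar_battery <- function(x, ...) {
  cat("<qsar_battery> classifiers: ",
      paste(names(x$classifiers), collapse = ", "),
      "; regressors: ", paste(names(x$regressors), collapse = ", "),
      "; pool of ", length(x$descriptor_pool), " descriptors; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Screen an untested compound set with a trained battery
#'
#' Produces per-compound transporter-activity profiles: every classifier's
#' call and applicability flag, the consensus calls (strict A, A+B, and the
#' `nnd`+`qd` pair), and — for compounds called active by at least one
#' classifier — a consensus pKi from the regression battery (leverage-
#' weighted over in-domain models).
#'
#' @param battery A `qsar_battery`.
#' @param newdata Descriptor tibble covering the battery's descriptor pool.
#' @return A `screening_profile` tibble; the per-model/consensus summary
#'   counts (a Table-2-shaped overview) are attached as
#'   `attr(, "summary")` and printed by [screening_summary()].
#' @export
run_screening <- function(battery, newdata) {
  stopifnot(inherits(battery, "qsar_battery"))
  missing <- setdiff(battery$descriptor_pool,
                     setdiff(names(newdata), "compound_id"))
  if (length(missing)) {
    abort(paste0("screening set lacks descriptors: ",
                 paste(missing, collapse = ", ")))
  }
  x <- newdata[c("compound_id", battery$descriptor_pool)]
  ids <- x$compound_id
  calls <- classifier_calls(battery, x)

  profile <- tibble::tibble(compound_id = ids)
  for (nm in names(battery$classifiers)) {
    profile[[nm]] <- calls$predictions[[nm]]$prediction
    profile[[paste0(nm, "_ad")]] <- calls$predictions[[nm]]$ad_flag
  }
  pm <- tibble::tibble(compound_id = ids,
                       nnc = calls$abstaining_labels$nnc,
                       nnd = calls$abstaining_labels$nnd,
                       qd = calls$abstaining_labels$qd)
  v_a <- consensus_classify(pm, mode = "strict")
  v_ab <- consensus_classify(pm, mode = "A+B")
  v_pair <- consensus_classify(pm[c("compound_id", "nnd", "qd")],
                               mode = "pairwise")
  profile$consensus_A <- v_a$combined_label
  profile$consensus_AB <- v_ab$combined_label
  profile$consensus_nnd_qd <- v_pair$combined_label

  # regression consensus for compounds with at least one active call
  any_active <- purrr::reduce(
    purrr::map(names(battery$classifiers),
               function(nm) !is.na(profile[[nm]]) & profile[[nm]] == "active"),
    `|`
  )
  profile$predicted_pKi <- NA_real_
  profile$n_regressors_in_ad <- NA_integer_
  if (any(any_active) && length(battery$regressors)) {
    xa <- x[any_active, ]
    long <- purrr::imap(battery$regressors, function(r, nm) {
      pr <- predict(r$model, xa)
      h <- leverage(r$leverage_model, xa)
      tibble::tibble(compound_id = pr$compound_id, model = nm,
                     prediction = as.numeric(pr$prediction),
                     leverage = unname(h[pr$compound_id]),
                     ad_flag = pr$ad_flag)
    }) |> dplyr::bind_rows()
    cons <- consensus_regression_battery(long)
    idx <- match(cons$compound_id, profile$compound_id)
    profile$predicted_pKi[idx] <- cons$consensus_weighted
    profile$n_regressors_in_ad[idx] <- cons$n_models_in_ad
  }

  single_rows <- purrr::imap(battery$classifiers, function(m, nm) {
    tibble::tibble(
      model = nm,
      n_in_ad = sum(calls$predictions[[nm]]$ad_flag),
      n_active = sum(profile[[nm]] == "active"),
      prediction_rate = 1
    )
  })
  cons_rows <- purrr::map2(
    list(v_a, v_ab, v_pair), c("A", "A+B", "nnd+qd"),
    function(v, nm) {
      pred <- v$combined_label != "no-prediction"
      tibble::tibble(model = nm, n_in_ad = NA_integer_,
                     n_active = sum(v$combined_label == "active"),
                     prediction_rate = mean(pred))
    }
  )
  summary_tbl <- dplyr::bind_rows(c(unname(single_rows), cons_rows))
  attr(profile, "summary") <- summary_tbl
  class(profile) <- c("screening_profile", class(profile))
  profile
}

#' Summary counts of a screening run
#' @param profile A `screening_profile` from [run_screening()].
#' @return Tibble with per-model/consensus in-domain counts, active counts
#'   and prediction rates.
#' @export
screening_summary <- function(profile) {
  s <- attr(profile, "summary")
  if (is.null(s)) abort("no summary attached; not a run_screening() result?")
  s
}
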