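# Shared fixtures and independent oracles for the test suite.

# The reference synthetic study conditions: 120 compounds, 40 descriptors,
# 5 informative, 50/70 class split, noise sd 0.2.
demo_spec <- function(seed = 9, ...) qsar_spec(noise_sd = 0.2, seed = seed, ...)

demo_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    .fixture_cache$dataset <- simulate_qsar_dataset(demo_spec())
  }
  .fixture_cache$dataset
}

# One full default-config battery, shared by the pipeline and acceptance
# tests (training it takes about a minute).
demo_battery <- function() {
  if (is.null(.fixture_cache$battery)) {
    .fixture_cache$battery <- run_modeling_pipeline(demo_dataset(), seed = 1)
  }
  .fixture_cache$battery
}

# A deliberately small pipeline configuration for determinism checks,
# exercising every stage at reduced budgets.
light_config <- function() {
  pipeline_config(
    ga_classif = ga_config(population_size = 10L, generations = 3L,
                           subset_min = 4L, subset_max = 10L, cv_folds = 3L),
    ga_qd = ga_config(population_size = 10L, generations = 3L,
                      subset_min = 4L, subset_max = 11L, cv_folds = 3L),
    ga_regression = ga_config(population_size = 8L, generations = 2L,
                              subset_min = 3L, subset_max = 8L,
                              cv_folds = 3L),
    cpann = cpann_config(grid_rows = 7L, grid_cols = 7L, epochs = 30L),
    cpann_regression = cpann_config(grid_rows = 6L, grid_cols = 6L,
                                    epochs = 30L)
  )
}

.fixture_cache <- new.env(parent = emptyenv())

# Build a tiny hand-rolled CP-ANN model (bypassing training) so lookup
# mechanics can be tested against known weights.
manual_cpann <- function(w, out, task = "classification", ed_crt = Inf) {
  structure(
    list(
      kohonen_weights = w,
      output_weights = out,
      grid_rows = nrow(w) %/% 2L + nrow(w) %% 2L, # unused by lookup
      grid_cols = 2L,
      descriptor_names = colnames(w),
      scaling = NULL,
      ed_crt = ed_crt,
      task = task,
      config = cpann_config(seed = 1),
      rmse_history = numeric(0),
      n_train = nrow(w)
    ),
    class = "cpann"
  )
}

scaled_tbl <- function(x) {
  # mark a numeric matrix/tibble as already scaled (identity scaling)
  tb <- tibble::as_tibble(as.data.frame(x))
  tb <- tibble::add_column(tb, compound_id = rownames(x) %||%
                             sprintf("c%02d", seq_len(nrow(x))), .before = 1)
  attr(tb, "scaling") <- structure(
    list(mean = setNames(rep(0, ncol(x)), colnames(x)),
         sd = setNames(rep(1, ncol(x)), colnames(x)),
         sd_convention = "population"),
    class = "scaling_params"
  )
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ------------------------------------------------

# Confusion tallies by explicit pairwise enumeration.
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (is.na(y_pred[i])) next
    if (y_true[i] == "active" && y_pred[i] == "active") tp <- tp + 1L
    if (y_true[i] == "inactive" && y_pred[i] == "inactive") tn <- tn + 1L
    if (y_true[i] == "inactive" && y_pred[i] == "active") fp <- fp + 1L
    if (y_true[i] == "active" && y_pred[i] == "inactive") fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Regression validation metrics written out longhand (spreadsheet-style),
# kept independent of the package's vectorized implementation.
oracle_regression_metrics <- function(obs, pred, train) {
  n <- length(obs)
  sq <- 0
  for (i in seq_len(n)) sq <- sq + (obs[i] - pred[i])^2
  rmse <- sqrt(sq / n)
  mtr <- sum(train) / length(train)
  sstr <- 0
  for (v in train) sstr <- sstr + (v - mtr)^2
  q2f3 <- 1 - (sq / n) / (sstr / length(train))
  mo <- sum(obs) / n; mp <- sum(pred) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (obs[i] - mo) * (pred[i] - mp)
    sxx <- sxx + (obs[i] - mo)^2
    syy <- syy + (pred[i] - mp)^2
  }
  r2 <- (sxy / sqrt(sxx * syy))^2
  ccc <- 2 * (sxy / n) / (sxx / n + syy / n + (mo - mp)^2)
  k0 <- sum(obs * pred) / sum(pred^2)
  ss0 <- 0
  for (i in seq_len(n)) ss0 <- ss0 + (obs[i] - k0 * pred[i])^2
  r0 <- 1 - ss0 / sxx
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r0)))
  list(R2 = r2, RMSE = rmse, Q2_F3 = q2f3, CCC = ccc, r0_2 = r0, rm2 = rm2)
}
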