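test_that("a single full-rate winner-only update overwrites the winner", {
  x <- tibble::tibble(compound_id = "c1", d1 = 0.3, d2 = -0.7)
  attr(x, "scaling") <- structure(
    list(mean = c(d1 = 0, d2 = 0), sd = c(d1 = 1, d2 = 1),
         sd_convention = "population"),
    class = "scaling_params"
  )
  m <- train_cpann(x, "active",
                   cpann_config(grid_rows = 2, grid_cols = 2, epochs = 1,
                                eta_max = 1, eta_min = 1, seed = 5))
  win <- find_winner(m, c(0.3, -0.7))
  expect_equal(win$distance, 0, tolerance = 1e-12)
  expect_equal(m$kohonen_weights[win$neuron, ], c(d1 = 0.3, d2 = -0.7))
  expect_equal(m$output_weights[win$neuron], 1) # target "active" = 1
  expect_equal(m$ed_crt, 0, tolerance = 1e-12)
})

test_that("training is deterministic in the seed", {
  d <- simulate_qsar_dataset(demo_spec())
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  cfg <- cpann_config(grid_rows = 5, grid_cols = 5, epochs = 20, seed = 3)
  a <- train_cpann(xs, d$activities$class, cfg)
  b <- train_cpann(xs, d$activities$class, cfg)
  expect_identical(a$kohonen_weights, b$kohonen_weights)
  expect_identical(a$output_weights, b$output_weights)
  cfg2 <- cpann_config(grid_rows = 5, grid_cols = 5, epochs = 20, seed = 4)
  c <- train_cpann(xs, d$activities$class, cfg2)
  expect_false(identical(a$kohonen_weights, c$kohonen_weights))
})

test_that("find_winner agrees with an exhaustive scan and breaks ties low", {
  d <- simulate_qsar_dataset(demo_spec())
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  m <- train_cpann(xs, d$activities$class,
                   cpann_config(grid_rows = 6, grid_cols = 6, epochs = 20,
                                seed = 2))
  set.seed(99)
  for (i in 1:200) {
    q <- rnorm(length(d$true_support), sd = 2)
    win <- find_winner(m, q)
    d2 <- apply(m$kohonen_weights, 1, function(w) sqrt(sum((w - q)^2)))
    expect_equal(win$neuron, which.min(d2))
    expect_equal(win$distance, min(d2), tolerance = 1e-12)
  }
  # exact tie between two neurons resolves to the lower row-major index
  w <- rbind(c(1, 0), c(1, 0), c(0, 5))
  colnames(w) <- c("d1", "d2")
  tie <- manual_cpann(w, c(0.1, 0.9, 0.5))
  expect_equal(find_winner(tie, c(1, 0))$neuron, 1L)
  expect_error(find_winner(tie, c(1, 0, 0)), "dimension")
})

test_that("noise-free data is memorized when neurons outnumber compounds", {
  spec <- qsar_spec(n_compounds = 60, n_descriptors = 15, n_informative = 5,
                    n_correlation_blocks = 2, noise_sd = 0, seed = 5)
  d <- simulate_qsar_dataset(spec)
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  m <- train_cpann(xs, d$activities$class,
                   cpann_config(grid_rows = 8, grid_cols = 8, epochs = 200,
                                seed = 5))
  acc <- mean(predict(m, xs)$prediction == d$activities$class)
  expect_gte(acc, 0.95)
  mr <- train_cpann(xs, d$activities$pKi,
                    cpann_config(grid_rows = 8, grid_cols = 8, epochs = 200,
                                 seed = 5))
  pr <- predict(mr, xs)
  expect_gte(cor(as.numeric(pr$prediction), d$activities$pKi)^2, 0.9)
  # training RMSE ends below where it starts and near its running minimum
  h <- mr$rmse_history
  expect_lt(h[length(h)], h[1])
  expect_lte(h[length(h)], min(h) * 1.1)
})

test_that("prediction flags follow the Euclidean-distance domain", {
  d <- simulate_qsar_dataset(demo_spec())
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  m <- train_cpann(xs, d$activities$class,
                   cpann_config(grid_rows = 6, grid_cols = 6, epochs = 40,
                                seed = 7))
  pr <- predict(m, xs)
  expect_true(all(pr$ad_flag)) # training distances never exceed their max
  far <- xs
  for (nm in setdiff(names(far), "compound_id")) far[[nm]] <- far[[nm]] + 100
  attr(far, "scaling") <- attr(xs, "scaling")
  expect_false(any(predict(m, far)$ad_flag))
  # in-domain fraction shrinks monotonically as the cutoff is lowered
  scr <- autoscale(simulate_screening_set(d, n = 100, seed = 1)[
    c("compound_id", d$true_support)], params = get_scaling(xs))
  fracs <- vapply(c(1, 0.75, 0.5, 0.25, 0.1), function(f) {
    m2 <- m
    m2$ed_crt <- m$ed_crt * f
    mean(predict(m2, scr)$ad_flag)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("the 0.5 output boundary is assigned to the active class", {
  w <- rbind(c(0, 0), c(4, 4))
  colnames(w) <- c("d1", "d2")
  m <- manual_cpann(w, c(0.5, 0.49))
  x <- scaled_tbl(matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE,
                         dimnames = list(c("a", "b"), c("d1", "d2"))))
  pr <- predict(m, x)
  expect_identical(pr$prediction, c("active", "inactive"))
})

test_that("vanishing learning rate leaves the map at its initialization", {
  d <- simulate_qsar_dataset(demo_spec())
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  short <- train_cpann(xs, d$activities$class,
                       cpann_config(grid_rows = 4, grid_cols = 4, epochs = 1,
                                    eta_max = 1e-9, eta_min = 1e-9, seed = 6))
  long <- train_cpann(xs, d$activities$class,
                      cpann_config(grid_rows = 4, grid_cols = 4, epochs = 40,
                                   eta_max = 1e-9, eta_min = 1e-9, seed = 6))
  expect_equal(short$kohonen_weights, long$kohonen_weights,
               tolerance = 1e-5)
})

test_that("degenerate training inputs are rejected", {
  x <- tibble::tibble(compound_id = c("a", "b"), d1 = c(1, NaN))
  expect_error(train_cpann(x, c("active", "inactive"), cpann_config(seed = 1)),
               "non-finite")
  expect_error(train_cpann(tibble::tibble(compound_id = character(),
                                          d1 = numeric()),
                           character(0), cpann_config(seed = 1)),
               "empty")
  expect_error(cpann_config(eta_max = 0.1, eta_min = 0.5), "eta")
})
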