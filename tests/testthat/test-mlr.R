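test_that("the leverage warning threshold reproduces its analytic anchor", {
  expect_identical(hat_star(11, 90), 0.4)
  expect_equal(hat_star(5, 60), 3 * 6 / 60)
})

test_that("coefficients agree with an independent linear-algebra solve", {
  set.seed(12)
  for (i in 1:5) {
    n <- 25; p <- 4
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("c%02d", 1:n), paste0("d", 1:p)))
    y <- rnorm(n)
    fit <- fit_mlr(scaled_tbl(X), y)
    Xa <- cbind(1, X)
    beta <- solve(t(Xa) %*% Xa, t(Xa) %*% y) # normal equations, by hand
    expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-8)
  }
})

test_that("noise-free linear targets are fitted exactly", {
  d <- simulate_qsar_dataset(qsar_spec(noise_sd = 0, nonlinearity_weight = 0,
                                       seed = 4))
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  m <- fit_mlr(xs, d$activities$pKi)
  pr <- predict(m, xs)
  expect_lt(max(abs(as.numeric(pr$prediction) - d$activities$pKi)), 1e-8)
})

test_that("leverages satisfy the hat-matrix identities", {
  d <- simulate_qsar_dataset(demo_spec())
  xs <- autoscale(d$descriptors[c("compound_id", d$true_support)])
  m <- fit_mlr(xs, d$activities$pKi)
  h <- leverage(m, xs)
  p1 <- length(d$true_support) + 1
  expect_equal(sum(h), p1, tolerance = 1e-8) # trace of the hat matrix
  expect_true(all(h >= 1 / 120 - 1e-12 & h <= 1 + 1e-12))
  # the training centroid attains the minimum 1/n (columns are centred)
  centroid <- xs[1, ]
  for (nm in setdiff(names(centroid), "compound_id")) centroid[[nm]] <- 0
  attr(centroid, "scaling") <- attr(xs, "scaling")
  expect_equal(unname(leverage(m, centroid)), 1 / 120, tolerance = 1e-10)
  # explicit hat-matrix diagonal on a small instance
  set.seed(3)
  Xs <- matrix(rnorm(30), 10, 3,
               dimnames = list(sprintf("c%02d", 1:10), paste0("d", 1:3)))
  ms <- fit_mlr(scaled_tbl(Xs), rnorm(10))
  Xa <- cbind(1, Xs)
  H <- Xa %*% solve(t(Xa) %*% Xa) %*% t(Xa)
  expect_equal(unname(leverage(ms, scaled_tbl(Xs))), unname(diag(H)),
               tolerance = 1e-8)
})

test_that("the applicability gate is strict in the leverage threshold", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("c%02d", 1:20), c("d1", "d2")))
  m <- fit_mlr(scaled_tbl(X), rnorm(20))
  q <- scaled_tbl(matrix(c(0, 0, 8, 8), 2, 2, byrow = TRUE,
                         dimnames = list(c("near", "far"), c("d1", "d2"))))
  pr <- predict(m, q)
  expect_identical(pr$ad_flag, pr$leverage <= m$hat_star)
  expect_true(pr$ad_flag[1])
  expect_false(pr$ad_flag[2])
  # a leverage a hair above the cut fails, at the cut passes
  m2 <- m
  m2$hat_star <- pr$leverage[2] + 1e-9
  expect_true(all(predict(m2, q)$ad_flag))
  m2$hat_star <- pr$leverage[2] - 1e-9
  expect_false(predict(m2, q)$ad_flag[2])
})

test_that("an intercept-only model predicts the training mean", {
  y <- c(1.2, 3.4, 2.2, 0.8)
  tb <- tibble::tibble(compound_id = sprintf("c%d", 1:4))
  m <- fit_mlr(tb, y)
  pr <- predict(m, tibble::tibble(compound_id = "new"))
  expect_equal(as.numeric(pr$prediction), mean(y))
})

test_that("rank-deficient designs are refused with the offending columns", {
  X <- matrix(rnorm(30), 15, 2,
              dimnames = list(sprintf("c%02d", 1:15), c("d1", "d2")))
  X <- cbind(X, d1_dup = X[, "d1"])
  expect_error(fit_mlr(scaled_tbl(X), rnorm(15)), "collinear")
  expect_error(fit_mlr(scaled_tbl(X[1:3, 1:2]), rnorm(3)), "more training")
})

test_that("model family ordering follows the planted response surface", {
  # Purely linear signal: OLS is exact, the lookup network is not.
  # Strongly nonlinear 2-descriptor signal: the network halves the OLS
  # error because the product term is invisible to a linear fit.
  rmse_of <- function(dd, seed) {
    sp <- split_dataset(dd$descriptors, dd$activities, c(0.75, 0.25),
                        seed = seed)
    pki <- setNames(dd$activities$pKi, dd$activities$compound_id)
    sub <- c("compound_id", dd$true_support)
    xt <- dd$descriptors[match(sp$train_ids, dd$descriptors$compound_id), sub]
    xv <- dd$descriptors[match(sp$validation_ids,
                               dd$descriptors$compound_id), sub]
    xs <- autoscale(xt)
    mlr <- fit_mlr(xs, pki[sp$train_ids])
    cp <- train_cpann(xs, pki[sp$train_ids],
                      cpann_config(grid_rows = 10, grid_cols = 10,
                                   epochs = 200, eta_max = 0.7, seed = seed))
    obs <- pki[sp$validation_ids]
    c(mlr = sqrt(mean((as.numeric(predict(mlr, xv)$prediction) - obs)^2)),
      cpann = sqrt(mean((as.numeric(predict(cp, xv)$prediction) - obs)^2)))
  }
  lin <- simulate_qsar_dataset(qsar_spec(n_descriptors = 10,
                                         n_informative = 2,
                                         n_correlation_blocks = 2,
                                         noise_sd = 0,
                                         nonlinearity_weight = 0, seed = 31))
  r_lin <- rmse_of(lin, 31)
  expect_lte(r_lin[["mlr"]], r_lin[["cpann"]])
  nl <- simulate_qsar_dataset(qsar_spec(n_descriptors = 10,
                                        n_informative = 2,
                                        n_correlation_blocks = 2,
                                        noise_sd = 0.05,
                                        nonlinearity_weight = 1, seed = 31))
  r_nl <- rmse_of(nl, 31)
  expect_lt(r_nl[["cpann"]], r_nl[["mlr"]])
})
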