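test_that("autoscale centres to zero mean and unit population sd", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 2))
  s <- autoscale(d$descriptors)
  m <- as.matrix(s[-1])
  expect_lt(max(abs(colMeans(m))), 1e-10)
  pop_sd <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  expect_lt(max(abs(pop_sd - 1)), 1e-10)
  # population-sd convention: a 2-row column (1, 3) scales to (-1, +1)
  two <- tibble::tibble(compound_id = c("a", "b"), d1 = c(1, 3))
  expect_equal(autoscale(two)$d1, c(-1, 1))
})

test_that("stored scaling params reproduce the fitted output and transfer", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 2))
  s <- autoscale(d$descriptors)
  p <- get_scaling(s)
  again <- autoscale(d$descriptors, params = p)
  expect_equal(as.matrix(again[-1]), as.matrix(s[-1]), tolerance = 1e-12)
  # new compounds are expressed in training units, not refit
  scr <- simulate_screening_set(d, n = 10, seed = 1)
  st <- autoscale(scr, params = p)
  expect_false(all(abs(colMeans(as.matrix(st[-1]))) < 1e-10))
})

test_that("autoscale refuses to fit through zero-variance columns", {
  bad <- tibble::tibble(compound_id = c("a", "b", "c"),
                        d1 = c(1, 2, 3), d2 = c(5, 5, 5))
  expect_error(autoscale(bad), "zero-variance")
})

test_that("zero-variance filter removes constant and near-constant columns", {
  tb <- tibble::tibble(compound_id = sprintf("c%d", 1:4),
                       keep = c(1, 2, 3, 4),
                       const = rep(2, 4),
                       tiny = 1 + c(0, 1e-8, 0, 1e-8) * 1e-4)
  out <- drop_zero_variance(tb)
  expect_identical(setdiff(names(out), "compound_id"), "keep")
  expect_identical(drop_zero_variance(tb["compound_id"] |>
                                        tibble::add_column(keep = 1:4)),
                   tibble::tibble(compound_id = tb$compound_id, keep = as.numeric(1:4)))
  expect_error(drop_zero_variance(tibble::tibble(compound_id = c("a", "b"),
                                                 z = c(1, 1))),
               "all descriptors")
})

test_that("intercorrelation filter keeps the earlier column of each pair", {
  set.seed(42)
  base <- rnorm(60)
  tb <- tibble::tibble(compound_id = sprintf("c%02d", 1:60),
                       a = base,
                       b = rnorm(60),
                       a_copy = base,
                       c = rnorm(60))
  out <- drop_intercorrelated(tb)
  expect_identical(setdiff(names(out), "compound_id"), c("a", "b", "c"))
  # orthogonal columns pass through untouched
  ortho <- tibble::tibble(compound_id = c("x", "y", "z"),
                          d1 = c(1, 0, 0), d2 = c(0, 1, 0))
  expect_identical(drop_intercorrelated(ortho), ortho)
})

test_that("survivors of the intercorrelation filter are pairwise below cut", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 6))
  out <- drop_intercorrelated(d$descriptors, threshold = 0.9)
  r <- abs(cor(as.matrix(out[-1])))
  expect_lte(max(r[upper.tri(r)]), 0.9)
  # exactly one survivor per planted correlation block
  for (block in d$correlation_blocks) {
    expect_equal(sum(block %in% names(out)), 1L)
  }
})

test_that("activity threshold is strict", {
  expect_identical(classify_by_threshold(c(1.31, 1.3, -0.5)),
                   c("active", "inactive", "inactive"))
  expect_error(classify_by_threshold(c(1, NA)), "finite")
})

test_that("splits honour the requested sizes", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 4))
  two <- split_dataset(d$descriptors, d$activities, c(0.75, 0.25), seed = 1)
  expect_length(two$train_ids, 90)
  expect_length(two$validation_ids, 30)
  three <- split_dataset(d$descriptors, d$activities, c(0.60, 0.25, 0.15),
                         method = "som", seed = 1)
  expect_length(three$test_ids, 30)
  expect_length(three$validation_ids, 18)
  expect_length(three$train_ids, 72)
})

test_that("splits are disjoint, exhaustive and deterministic for all methods", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 4))
  for (method in c("random", "som")) {
    for (seed in c(1, 7)) {
      sp <- split_dataset(d$descriptors, d$activities, c(0.6, 0.25, 0.15),
                          method = method, seed = seed)
      parts <- list(sp$train_ids, sp$test_ids, sp$validation_ids)
      all_ids <- unlist(parts)
      expect_equal(sort(all_ids), sort(d$descriptors$compound_id))
      expect_equal(anyDuplicated(all_ids), 0L)
      again <- split_dataset(d$descriptors, d$activities, c(0.6, 0.25, 0.15),
                             method = method, seed = seed)
      expect_identical(sp, again)
      # both classes survive in training
      cls <- d$activities$class[match(sp$train_ids,
                                      d$activities$compound_id)]
      expect_setequal(unique(cls), c("active", "inactive"))
    }
  }
})

test_that("split manifests round-trip through JSON", {
  d <- simulate_qsar_dataset(qsar_spec(seed = 4))
  sp <- split_dataset(d$descriptors, d$activities, c(0.75, 0.25), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_identical(sp2$train_ids, sp$train_ids)
  expect_identical(sp2$validation_ids, sp$validation_ids)
})
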