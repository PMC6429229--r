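verdicts <- function(labels, mode) {
  per <- tibble::as_tibble(as.data.frame(labels,
                                         stringsAsFactors = FALSE))
  names(per) <- paste0("m", seq_along(per))
  per <- tibble::add_column(per,
                            compound_id = sprintf("c%d", seq_len(nrow(per))),
                            .before = 1)
  consensus_classify(per, mode = mode)
}

test_that("agreement typing follows the consensus protocol", {
  v <- verdicts(matrix(c("active", "active", "active"), 1), "strict")
  expect_identical(v$combined_label, "active")
  expect_identical(v$agreement_type, "A")

  split_vote <- matrix(c("active", "active", "inactive"), 1)
  expect_identical(verdicts(split_vote, "strict")$combined_label,
                   "no-prediction")
  ab <- verdicts(split_vote, "A+B")
  expect_identical(ab$combined_label, "active")
  expect_identical(ab$agreement_type, "B")

  two_disagree <- verdicts(matrix(c("active", "inactive"), 1), "pairwise")
  expect_identical(two_disagree$combined_label, "no-prediction")
  expect_identical(two_disagree$agreement_type, "none")
  two_agree <- verdicts(matrix(c("inactive", "inactive"), 1), "pairwise")
  expect_identical(two_agree$combined_label, "inactive")
})

test_that("out-of-domain abstentions block strict and A+B consensus", {
  with_na <- matrix(c("active", NA, "active"), 1)
  expect_identical(verdicts(with_na, "strict")$combined_label,
                   "no-prediction")
  expect_identical(verdicts(with_na, "A+B")$combined_label, "no-prediction")
  expect_identical(verdicts(matrix(c("active", NA), 1),
                            "pairwise")$combined_label, "no-prediction")
})

test_that("model-count contracts are enforced", {
  expect_error(verdicts(matrix(c("active", "active"), 1), "strict"), "3")
  expect_error(verdicts(matrix(rep("active", 3), 1), "pairwise"), "2")
})

test_that("strict coverage is nested in A+B coverage for any label pattern", {
  set.seed(17)
  for (i in 1:20) {
    labs <- matrix(sample(c("active", "inactive", NA), 60, replace = TRUE,
                          prob = c(.4, .4, .2)), 20, 3)
    a <- verdicts(labs, "strict")
    ab <- verdicts(labs, "A+B")
    predicted_a <- a$combined_label != "no-prediction"
    predicted_ab <- ab$combined_label != "no-prediction"
    expect_true(all(predicted_ab[predicted_a])) # A implies A+B
    expect_lte(mean(predicted_a), mean(predicted_ab)) # PR(A) <= PR(A+B)
    expect_identical(a$combined_label[predicted_a],
                     ab$combined_label[predicted_a])
  }
})

test_that("the weighted average response follows the stated formula", {
  expect_equal(weighted_average_response(c(1, 3), c(0.2, 0.2)), 2)
  expect_equal(weighted_average_response(c(1, 3), c(0.1, 0.3)), 1.5)
  expect_equal(weighted_average_response(5.5, 0.7), 5.5)
  expect_error(weighted_average_response(c(1, 2), c(0.1, 0)), "positive")
  # convexity: always inside the span of the model responses
  set.seed(21)
  for (i in 1:50) {
    y <- rnorm(4); h <- runif(4, 0.05, 1)
    w <- weighted_average_response(y, h)
    expect_gte(w, min(y) - 1e-12)
    expect_lte(w, max(y) + 1e-12)
  }
})

test_that("Hamming model distance counts unshared descriptors", {
  expect_equal(hamming_model_distance(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0)), 0)
  expect_equal(hamming_model_distance(c(1, 0, 1, 1, 0), c(0, 1, 1, 1, 0)), 2)
  a <- c(rep(1, 4), rep(0, 6)); b <- c(rep(0, 4), rep(1, 3), rep(0, 3))
  expect_equal(hamming_model_distance(a, b), 7) # disjoint: 4 + 3
  expect_error(hamming_model_distance(c(1, 0), c(1, 0, 1)), "length")
})

test_that("the regression battery gates on the applicability domain", {
  preds <- tibble::tibble(
    compound_id = rep(c("c1", "c2", "c3"), each = 3),
    model = rep(c("M1", "M2", "M3"), 3),
    prediction = c(2, 2, 2, 1, 3, 9, 4, 5, 6),
    leverage = c(.2, .2, .2, .1, .3, .1, .2, .2, .2),
    ad_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  out <- consensus_regression_battery(preds)
  expect_equal(out$consensus_weighted[out$compound_id == "c1"], 2)
  # c2: out-of-domain M3 (prediction 9) is excluded from both averages
  expect_equal(out$consensus_weighted[out$compound_id == "c2"],
               weighted_average_response(c(1, 3), c(.1, .3)))
  expect_equal(out$consensus_mean[out$compound_id == "c2"], 2)
  expect_true(is.na(out$consensus_weighted[out$compound_id == "c3"]))
  expect_equal(out$n_models_in_ad, c(3L, 2L, 0L))
  expect_error(consensus_regression_battery(preds[, -3]), "columns")
})

test_that("consensus verdicts improve accuracy on the jointly predicted set", {
  rep_tbl <- demo_battery()$validation$classification
  singles <- rep_tbl[rep_tbl$model %in% c("nnc", "nnd", "qd"), ]
  a_row <- rep_tbl[rep_tbl$model == "A", ]
  ab_row <- rep_tbl[rep_tbl$model == "A+B", ]
  expect_gte(a_row$acc_standard, max(singles$acc_standard) - 0.02)
  expect_lte(a_row$PR, min(singles$PR))
  expect_lte(a_row$PR, ab_row$PR)
})
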