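#' Consensus classification across a battery of models
#'
#' Combines per-model class calls compound by compound. Out-of-domain
#' models abstain (`NA`). Three modes follow the usual consensus protocol:
#' \describe{
#'   \item{`"strict"`}{three models; a combined label only when all three
#'     predicted and agree (agreement type A).}
#'   \item{`"A+B"`}{three models; all three must have predicted, and the
#'     majority label is returned with at most one disagreement — type A
#'     when unanimous, type B with exactly one dissent.}
#'   \item{`"pairwise"`}{two models; a label only when both predicted and
#'     agree.}
#' }
#'
#' @param per_model A data frame / tibble with a `compound_id` column and
#'   one column of labels per model (`"active"`/`"inactive"`/`NA`), or a
#'   character matrix with compound ids as rownames.
#' @param mode `"strict"`, `"A+B"` or `"pairwise"`.
#' @return A `consensus_verdict` tibble: `compound_id`, the per-model
#'   columns, `combined_label` (`"active"`/`"inactive"`/`"no-prediction"`),
#'   `agreement_type` (`"A"`/`"B"`/`"none"`).
#' @export
#' @examples
#' per <- tibble::tibble(compound_id = c("c1", "c2"),
#'                       m1 = c("active", "active"),
#'                       m2 = c("active", "active"),
#'                       m3 = c("active", "inactive"))
#' consensus_classify(per, mode = "A+B")
consensus_classify <- function(per_model, mode = c("strict", "A+B", "pairwise")) {
  mode <- match.arg(mode)
  if (is.matrix(per_model)) {
    per_model <- tibble::as_tibble(per_model, rownames = "compound_id")
  }
  stopifnot(is.data.frame(per_model), "compound_id" %in% names(per_model))
  model_cols <- setdiff(names(per_model), "compound_id")
  m <- length(model_cols)
  need <- if (mode == "pairwise") 2L else 3L
  if (m != need) {
    abort(sprintf("mode '%s' needs exactly %d model columns, got %d",
                  mode, need, m))
  }
  labs <- as.matrix(per_model[model_cols])
  ok <- labs %in% c("active", "inactive") | is.na(labs)
  if (!all(ok)) abort("labels must be active/inactive/NA")

  verdict <- t(apply(labs, 1L, consensus_vote, mode = mode))
  out <- per_model
  out$combined_label <- unname(verdict[, 1L])
  out$agreement_type <- unname(verdict[, 2L])
  class(out) <- c("consensus_verdict", class(out))
  out
}

# One compound's vote. Returns c(label, agreement_type).
consensus_vote <- function(labels, mode) {
  n_abstain <- sum(is.na(labels))
  voted <- labels[!is.na(labels)]
  none <- c("no-prediction", "none")
  if (mode == "pairwise") {
    if (n_abstain > 0L || voted[1L] != voted[2L]) return(none)
    return(c(voted[1L], "A"))
  }
  # strict and A+B both require all three models to have predicted
  if (n_abstain > 0L) return(none)
  n_active <- sum(voted == "active")
  unanimous <- n_active %in% c(0L, 3L)
  if (mode == "strict") {
    if (unanimous) return(c(voted[1L], "A"))
    return(none)
  }
  # A+B: majority with at most one dissent (always true for 3 voters)
  majority <- if (n_active >= 2L) "active" else "inactive"
  c(majority, if (unanimous) "A" else "B")
}

#' Leverage-weighted consensus of regression responses
#'
#' The weighted average response over a battery of models,
#' \eqn{\bar y_w = \sum_k (y_k / h_k) / \sum_k (1 / h_k)}: each model's
#' response is weighted by the inverse of its leverage, so models for which
#' the compound is more central (lower leverage, more reliable) weigh more.
#' With equal leverages this reduces to the arithmetic mean, and the result
#' always lies within `[min(y), max(y)]`.
#'
#' @param y Numeric vector of per-model responses for one compound.
#' @param h Numeric vector of matching leverages, all strictly positive.
#' @return The consensus response (scalar).
#' @export
#' @examples
#' weighted_average_response(c(1, 3), c(0.2, 0.2)) # 2
#' weighted_average_response(c(1, 3), c(0.1, 0.3)) # 1.5
weighted_average_response <- function(y, h) {
  stopifnot(length(y) == length(h), length(y) >= 1L)
  if (any(h <= 0)) abort("all leverages must be strictly positive")
  sum(y / h) / sum(1 / h)
}

#' Hamming distance between two models' descriptor masks
#'
#' The number of descriptors not shared: positions selected by one model
#' but not the other, in either direction. A model-diversity measure over a
#' shared descriptor pool.
#'
#' @param mask_i,mask_j Logical/0-1 vectors of equal length.
#' @return Integer distance.
#' @export
#' @examples
#' hamming_model_distance(c(1, 0, 1, 1, 0), c(0, 1, 1, 1, 0)) # 2
hamming_model_distance <- function(mask_i, mask_j) {
  if (length(mask_i) != length(mask_j)) {
    abort("masks must share the descriptor pool length")
  }
  sum(xor(as.logical(mask_i), as.logical(mask_j)))
}

#' Consensus regression over a battery with applicability gating
#'
#' Applies the leverage-weighted average (and, alongside, the simple mean)
#' over the models for which each compound is inside the applicability
#' domain. Compounds outside every model's domain get no prediction (`NA`).
#'
#' @param predictions Long tibble with columns `compound_id`, `model`,
#'   `prediction` (numeric), `leverage` (> 0), `ad_flag` (logical).
#' @return Tibble with `compound_id`, `n_models_in_ad`,
#'   `consensus_weighted`, `consensus_mean`.
#' @export
consensus_regression_battery <- function(predictions) {
  req <- c("compound_id", "model", "prediction", "leverage", "ad_flag")
  missing <- setdiff(req, names(predictions))
  if (length(missing)) {
    abort(paste0("predictions lack columns: ", paste(missing, collapse = ", ")))
  }
  predictions |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      n_models_in_ad = sum(.data$ad_flag),
      consensus_weighted = if (any(.data$ad_flag)) {
        weighted_average_response(.data$prediction[.data$ad_flag],
                                  .data$leverage[.data$ad_flag])
      } else NA_real_,
      consensus_mean = if (any(.data$ad_flag)) {
        mean(.data$prediction[.data$ad_flag])
      } else NA_real_,
      .groups = "drop"
    )
}
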