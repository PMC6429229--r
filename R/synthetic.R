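#' Specification of a synthetic transporter-inhibition dataset
#'
#' Describes the statistical shape of a simulated QSAR modelling set:
#' standard-normal molecular descriptors, a planted linear plus mildly
#' nonlinear structure-activity signal on a known descriptor subset,
#' Gaussian noise on the activity, and blocks of near-duplicate descriptor
#' columns that give the intercorrelation filter work to do. The defaults
#' mirror a bilitranslocase inhibition study design: 120 compounds, a
#' 50-active / 70-inactive split at the pKi > 1.3 activity cut.
#'
#' @param n_compounds Number of compounds (rows).
#' @param n_descriptors Number of descriptor columns.
#' @param n_informative Number of descriptors carrying signal.
#' @param active_fraction Target fraction of active compounds, in (0, 1).
#' @param activity_threshold Activity cut on the pKi scale; compounds with
#'   pKi strictly above it are labelled active.
#' @param noise_sd Standard deviation of Gaussian noise added to pKi.
#' @param nonlinearity_weight Weight in `[0, 1]` of a pairwise product of the
#'   first two informative descriptors, a mild nonlinearity that a
#'   counter-propagation network can exploit but a linear model cannot.
#' @param correlation_block_size Number of near-duplicate columns per
#'   correlated block (pairwise |r| > 0.9 within a block).
#' @param n_correlation_blocks Number of correlated blocks planted among the
#'   uninformative columns.
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return An object of class `qsar_spec` (a named list).
#' @export
#' @examples
#' qsar_spec(seed = 7)
qsar_spec <- function(n_compounds = 120L,
                      n_descriptors = 40L,
                      n_informative = 5L,
                      active_fraction = 50 / 120,
                      activity_threshold = 1.3,
                      noise_sd = 0.2,
                      nonlinearity_weight = 0.3,
                      correlation_block_size = 3L,
                      n_correlation_blocks = 4L,
                      seed = 1L) {
  spec <- list(
    n_compounds = check_count(n_compounds, "n_compounds", min = 2L),
    n_descriptors = check_count(n_descriptors, "n_descriptors"),
    n_informative = check_count(n_informative, "n_informative"),
    active_fraction = check_fraction(active_fraction, "active_fraction"),
    activity_threshold = as.numeric(activity_threshold),
    noise_sd = as.numeric(noise_sd),
    nonlinearity_weight = as.numeric(nonlinearity_weight),
    correlation_block_size = check_count(correlation_block_size,
                                         "correlation_block_size"),
    n_correlation_blocks = check_count(n_correlation_blocks,
                                       "n_correlation_blocks", min = 0L),
    seed = as.integer(seed)
  )
  if (spec$n_informative > spec$n_descriptors) {
    abort("`n_informative` cannot exceed `n_descriptors`")
  }
  if (spec$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (spec$nonlinearity_weight < 0 || spec$nonlinearity_weight > 1) {
    abort("`nonlinearity_weight` must lie in [0, 1]")
  }
  extra <- spec$n_correlation_blocks * (spec$correlation_block_size - 1L)
  if (spec$n_informative + spec$n_correlation_blocks + extra > spec$n_descriptors) {
    abort("descriptor pool too small for the requested correlation blocks")
  }
  structure(spec, class = "qsar_spec")
}

#' @export
print.qsar_spec <- function(x, ...) {
  cat("<qsar_spec> ", x$n_compounds, " compounds x ", x$n_descriptors,
      " descriptors (", x$n_informative, " informative), active fraction ",
      signif(x$active_fraction, 3), ", noise sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Within-block correlation used when planting near-duplicate columns.
BLOCK_RHO <- 0.95

# Draw the descriptor matrix implied by a spec: iid N(0,1) columns, then
# near-duplicate blocks planted among the uninformative columns. Returns the
# matrix plus the block layout so screening sets can reuse it.
draw_descriptors <- function(spec, n, ids) {
  p <- spec$n_descriptors
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("MD%03d", seq_len(p))
  rownames(x) <- ids
  blocks <- list()
  if (spec$n_correlation_blocks > 0L && spec$correlation_block_size > 1L) {
    free <- setdiff(seq_len(p), seq_len(spec$n_informative))
    k <- spec$correlation_block_size
    for (b in seq_len(spec$n_correlation_blocks)) {
      members <- free[seq_len(k)]
      free <- free[-seq_len(k)]
      lead <- members[1L]
      for (j in members[-1L]) {
        x[, j] <- BLOCK_RHO * x[, lead] +
          sqrt(1 - BLOCK_RHO^2) * rnorm(n)
      }
      blocks[[b]] <- colnames(x)[members]
    }
  }
  list(x = x, blocks = blocks)
}

#' Simulate a transporter-inhibition QSAR dataset
#'
#' Generates descriptors and activities with the structure declared by a
#' [qsar_spec()]: pKi is a linear combination of the informative descriptors
#' plus a weighted product of the first two of them and Gaussian noise. The
#' intercept is calibrated by a quantile shift so that the realized
#' active/inactive split matches `active_fraction` exactly (ties aside),
#' leaving the descriptor distribution untouched. Class labels follow the
#' strict rule pKi > `activity_threshold`.
#'
#' @param spec A [qsar_spec()].
#' @return An object of class `qsar_dataset`: a list with `descriptors`
#'   (tibble, first column `compound_id`), `activities` (tibble with
#'   `compound_id`, `pKi`, `class`), `true_support` (names of informative
#'   descriptors), `true_coefficients` (named vector incl. `(Intercept)`),
#'   `correlation_blocks`, and the `spec`.
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 7))
#' table(d$activities$class)
simulate_qsar_dataset <- function(spec = qsar_spec()) {
  stopifnot(inherits(spec, "qsar_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    ids <- sprintf("C%03d", seq_len(n))
    drawn <- draw_descriptors(spec, n, ids)
    x <- drawn$x
    support <- colnames(x)[seq_len(spec$n_informative)]
    beta <- runif(spec$n_informative, 0.5, 1.5) *
      sample(c(-1, 1), spec$n_informative, replace = TRUE)
    names(beta) <- support
    signal <- as.vector(x[, support, drop = FALSE] %*% beta)
    if (spec$n_informative >= 2L) {
      signal <- signal +
        spec$nonlinearity_weight * x[, support[1L]] * x[, support[2L]]
    }
    y_raw <- signal + rnorm(n, sd = spec$noise_sd)

    # Quantile-shift calibration: place the activity cut midway between the
    # k-th and (k+1)-th largest raw response so exactly k compounds fall
    # strictly above the threshold.
    k <- round(n * spec$active_fraction)
    k <- min(max(k, 1L), n - 1L)
    srt <- sort(y_raw, decreasing = TRUE)
    cut_raw <- (srt[k] + srt[k + 1L]) / 2
    intercept <- spec$activity_threshold - cut_raw
    pki <- y_raw + intercept

    activities <- tibble::tibble(
      compound_id = ids,
      pKi = unname(pki),
      class = unname(classify_by_threshold(pki, spec$activity_threshold))
    )
    structure(
      list(
        descriptors = desc_tbl(x),
        activities = activities,
        true_support = support,
        true_coefficients = c("(Intercept)" = intercept, beta),
        correlation_blocks = drawn$blocks,
        spec = spec
      ),
      class = "qsar_dataset"
    )
  })
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("<qsar_dataset> ", nrow(x$descriptors), " compounds x ",
      ncol(x$descriptors) - 1L, " descriptors; ",
      sum(x$activities$class == "active"), " active / ",
      sum(x$activities$class == "inactive"), " inactive (pKi > ",
      x$spec$activity_threshold, ")\n", sep = "")
  invisible(x)
}

#' Draw a screening set from a dataset's descriptor distribution
#'
#' Samples new compounds from the same generating distribution as the
#' template dataset (same column names, same marginals and correlated-block
#' layout) without any activity column, emulating an untested compound
#' library to be screened against trained models.
#'
#' @param template A `qsar_dataset` produced by [simulate_qsar_dataset()].
#' @param n Number of screening compounds; default 300.
#' @param seed Integer seed.
#' @return A descriptor tibble (first column `compound_id`, prefix "S").
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 7))
#' scr <- simulate_screening_set(d, n = 10, seed = 1)
simulate_screening_set <- function(template, n = 300L, seed = 1L) {
  stopifnot(inherits(template, "qsar_dataset"))
  n <- check_count(n, "n")
  with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n))
    drawn <- draw_descriptors(template$spec, n, ids)
    desc_tbl(drawn$x)
  })
}

#' Write a synthetic dataset to delimited text plus a JSON sidecar
#'
#' Descriptors and activities go to comma-separated files with a header row
#' and `compound_id` first; the planted truth (support, coefficients, block
#' layout) goes to a small JSON sidecar usable as a test oracle.
#'
#' @param dataset A `qsar_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qsar_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    descriptors = file.path(dir, "descriptors.csv"),
    activities = file.path(dir, "activities.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(dataset$descriptors, paths[["descriptors"]])
  readr::write_csv(dataset$activities, paths[["activities"]])
  jsonlite::write_json(
    list(
      true_support = dataset$true_support,
      true_coefficients = as.list(dataset$true_coefficients),
      correlation_blocks = dataset$correlation_blocks,
      spec = unclass(dataset$spec)
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
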