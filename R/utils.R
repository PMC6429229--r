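# Internal helpers shared across modules.

# Descriptor tables travel as tibbles whose first column is `compound_id`;
# numeric work happens on a plain matrix with compound ids as rownames.
desc_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"compound_id" %in% names(data)) {
    abort("descriptor table must have a `compound_id` column")
  }
  ids <- as.character(data$compound_id)
  if (anyDuplicated(ids)) abort("duplicate compound ids in descriptor table")
  x <- as.matrix(data[setdiff(names(data), "compound_id")])
  if (nrow(x) > 0L && ncol(x) > 0L && !is.numeric(x)) {
    abort("descriptor columns must be numeric")
  }
  storage.mode(x) <- "double"
  if (anyDuplicated(colnames(x))) abort("duplicate descriptor names")
  rownames(x) <- ids
  x
}

desc_tbl <- function(x) {
  tibble::as_tibble(as.data.frame(x), .name_repair = "minimal") |>
    tibble::add_column(compound_id = rownames(x), .before = 1)
}

# Run `expr` under a private RNG stream so package functions never disturb
# the caller's random state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly in (0, 1)", name))
  }
  as.numeric(x)
}

# sample() treats a length-1 numeric as 1:x; these wrappers always treat
# the first argument as the set itself.
sample_vec <- function(v, k = length(v)) v[sample.int(length(v), k)]

# Report rounding used in Table-1-shaped outputs: IEEE round-half-even at
# two decimals, the convention stated in the package docs.
round2 <- function(x) round(x, 2)
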