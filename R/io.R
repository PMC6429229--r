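# Delimited-text readers/writers for descriptor and activity tables.
# Comma- or tab-separated, autodetected from the extension (.tsv/.tab ->
# tab) with a sniff of the header line as fallback; header row mandatory;
# first column is the compound id.

detect_delim <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) return("\t")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a descriptor table from delimited text
#'
#' @param path CSV or TSV file; header row mandatory, first column is the
#'   compound identifier (renamed to `compound_id`).
#' @return Descriptor tibble.
#' @export
read_descriptors <- function(path) {
  tb <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  names(tb)[1L] <- "compound_id"
  tb$compound_id <- as.character(tb$compound_id)
  desc_matrix(tb) # validates ids/names/numeric
  tb
}

#' Read an activity table from delimited text
#'
#' Expects a compound-id first column and a `pKi` and/or `class` column;
#' when only `pKi` is present the class is derived with
#' [classify_by_threshold()].
#'
#' @param path CSV or TSV file.
#' @param threshold Activity cut used when deriving class from pKi.
#' @return Tibble with `compound_id`, optional `pKi`, `class`.
#' @export
read_activities <- function(path, threshold = 1.3) {
  tb <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  names(tb)[1L] <- "compound_id"
  tb$compound_id <- as.character(tb$compound_id)
  if (!"class" %in% names(tb)) {
    if (!"pKi" %in% names(tb)) abort("activity table needs `pKi` or `class`")
    tb$class <- classify_by_threshold(tb$pKi, threshold)
  } else if ("pKi" %in% names(tb)) {
    implied <- classify_by_threshold(tb$pKi, threshold)
    if (!all(implied == tb$class)) {
      abort("`class` column inconsistent with pKi at the stated threshold")
    }
  }
  tb
}

#' Write a split manifest as JSON
#'
#' @param split A `dataset_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a split manifest written by [write_split()]
#' @param path JSON path.
#' @return A `dataset_split`.
#' @export
read_split <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "dataset_split")
}
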