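#' Read a beta-value matrix
#'
#' Reads a probes-by-samples table of methylation fractions. The first
#' column holds probe identifiers; every other column is one sample.
#' Values must lie in \[0, 1\]; empty cells are kept as `NA` (missing is
#' allowed, out-of-range is not).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) picks tab for `.tsv`/
#'   `.txt` files and comma otherwise.
#' @return A tibble with character column `probe_id` followed by one
#'   numeric column per sample.
#' @export
read_beta_matrix <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(tbl)[1] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  validate_beta(tbl, context = path)
  tbl
}

#' Write a beta-value matrix
#'
#' @param beta Beta tibble as returned by [read_beta_matrix()].
#' @param path Output path; delimiter follows the file extension as in
#'   [read_beta_matrix()].
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  readr::write_delim(beta, path, delim = guess_delim(path), na = "")
  invisible(path)
}

guess_delim <- function(path) {
  if (grepl("\\.(tsv|txt)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
}

#' Validate a beta tibble
#'
#' Checks the layout invariants: a `probe_id` first column with no
#' duplicates, no duplicated sample columns, and all non-missing values in
#' \[0, 1\]. Violations raise an error naming the offending probe and
#' sample.
#'
#' @param beta Beta tibble.
#' @param context Optional label (e.g. a file path) used in error messages.
#' @return `beta`, invisibly.
#' @export
validate_beta <- function(beta, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" in ", context)
  if (!is.data.frame(beta) || ncol(beta) < 2L) {
    abort(paste0("beta matrix", where, " needs a probe_id column plus >= 1 sample column"))
  }
  if (names(beta)[1] != "probe_id") {
    abort(paste0("first column of a beta matrix must be 'probe_id', got '",
                 names(beta)[1], "'", where))
  }
  dup <- beta$probe_id[duplicated(beta$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate probe ids", where, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  smp <- names(beta)[-1]
  if (anyDuplicated(smp)) {
    abort(paste0("duplicate sample ids", where, ": ",
                 paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  }
  for (s in smp) {
    v <- beta[[s]]
    if (!is.numeric(v)) {
      abort(paste0("sample column '", s, "'", where, " is not numeric"))
    }
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      abort(paste0("beta value out of [0,1]", where, ": probe ",
                   beta$probe_id[bad[1]], ", sample ", s,
                   " (value ", format(v[bad[1]]), ")"))
    }
  }
  invisible(beta)
}

#' Convert between beta tibbles and numeric matrices
#'
#' `beta_to_matrix()` returns a probes-by-samples numeric matrix with
#' probe ids as rownames; `matrix_to_beta()` is its inverse.
#'
#' @param beta Beta tibble.
#' @param m Numeric matrix with probe rownames and sample colnames.
#' @return A matrix, or a beta tibble.
#' @export
beta_to_matrix <- function(beta) {
  m <- as.matrix(beta[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- beta$probe_id
  m
}

#' @rdname beta_to_matrix
#' @export
matrix_to_beta <- function(m) {
  dplyr::bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}

#' Align a beta matrix to a sample sheet
#'
#' Restricts the beta matrix to the samples shared with the sheet and
#' reorders its columns to the sheet's order.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @return Beta tibble whose sample columns match
#'   `intersect(sheet$sample_id, samples(beta))` in sheet order.
#' @export
align_samples <- function(beta, sheet) {
  validate_beta(beta)
  keep <- intersect(sheet$sample_id, names(beta)[-1])
  if (length(keep) == 0) {
    abort("no samples shared between beta matrix and sample sheet")
  }
  beta[, c("probe_id", keep)]
}
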