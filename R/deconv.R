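#' Read a cell-type reference panel
#'
#' @param path TSV with a `probe_id` column followed by one column of
#'   reference beta values per sorted cell type.
#' @return Tibble reference panel.
#' @export
read_cell_reference <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "probe_id"
  validate_beta(tbl, context = path)
  if (ncol(tbl) < 3) abort("reference panel needs >= 2 cell types")
  tbl
}

#' Estimate blood cell-type proportions
#'
#' Reference-based deconvolution: for each sample the proportions `pi`
#' minimise `|| beta_s - R pi ||^2` subject to `pi >= 0` and
#' `sum(pi) = 1` (a simplex-constrained least squares solved as a
#' quadratic program). Deterministic; proportions sum to one up to solver
#' tolerance and are renormalised.
#'
#' @param beta Beta tibble containing the reference CpGs (extra probes are
#'   ignored).
#' @param reference Reference panel tibble (`probe_id` + one column per
#'   cell type), e.g. from [read_cell_reference()] or
#'   [simulate_cohort()]`$cell_reference`.
#' @return Tibble with `sample_id` and one proportion column per cell type.
#' @export
estimate_cell_proportions <- function(beta, reference) {
  validate_beta(beta)
  validate_beta(reference)
  cell_types <- names(reference)[-1]
  k <- length(cell_types)
  if (k < 2) abort("reference panel needs >= 2 cell types")
  shared <- intersect(reference$probe_id, beta$probe_id)
  if (length(shared) < k) {
    abort(paste0("only ", length(shared), " reference CpGs found in beta matrix; need >= ", k))
  }
  R <- beta_to_matrix(reference)[shared, , drop = FALSE]
  if (qr(R)$rank < k) abort("reference panel is rank deficient")
  B <- beta_to_matrix(beta)[shared, , drop = FALSE]

  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  fit_one <- function(b) {
    ok <- !is.na(b)
    if (sum(ok) < k) abort("too many missing values at reference CpGs for a sample")
    Rk <- R[ok, , drop = FALSE]
    sol <- quadprog::solve.QP(Dmat = crossprod(Rk),
                              dvec = crossprod(Rk, b[ok]),
                              Amat = Amat, bvec = bvec, meq = 1)
    p <- pmax(sol$solution, 0)
    p / sum(p)
  }
  props <- t(apply(B, 2, fit_one))
  colnames(props) <- cell_types
  dplyr::bind_cols(tibble(sample_id = colnames(B)), as_tibble(props))
}

#' Cell-proportion covariate block
#'
#' Drops one cell type (neutrophils by default, the dominant fraction in
#' whole blood) so the remaining proportions are free of the sum-to-one
#' collinearity and can enter a design matrix.
#'
#' @param proportions Tibble from [estimate_cell_proportions()].
#' @param exclude Cell type to drop.
#' @return Tibble with `sample_id` and the kept proportion columns.
#' @export
covariate_block <- function(proportions, exclude = "Neu") {
  types <- setdiff(names(proportions), "sample_id")
  if (!exclude %in% types) {
    abort(paste0("cell type '", exclude, "' not present (have: ",
                 paste(types, collapse = ", "), ")"))
  }
  dplyr::select(proportions, "sample_id", dplyr::all_of(setdiff(types, exclude)))
}
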