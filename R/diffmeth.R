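#' Build the differential-methylation design matrix
#'
#' Assembles the per-sample design used by the covariate-adjusted model:
#' intercept, case indicator (control = 0, case = 1), chronological age,
#' sex indicator (M = 1), the non-collinear cell-proportion block, and the
#' DNAm-age residual. Only samples whose role is in `roles` enter the
#' design. The matrix must be full column rank; if not, the error names
#' the collinear columns.
#'
#' @param sheet Sample sheet.
#' @param cell_covariates Optional tibble from [covariate_block()]
#'   (`sample_id` + proportion columns).
#' @param clock_residuals Optional tibble with `sample_id` and `residual`
#'   (from [age_acceleration()]).
#' @param include_age,include_sex Include the age / sex covariates.
#' @param roles Roles defining the modeled samples.
#' @return Numeric design matrix with sample-id rownames.
#' @export
build_design <- function(sheet, cell_covariates = NULL, clock_residuals = NULL,
                         include_age = TRUE, include_sex = TRUE,
                         roles = c("discovery_case", "discovery_control")) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- dplyr::filter(sheet, .data$role %in% roles)
  if (nrow(sheet) == 0) abort("no samples with modeling roles in sheet")
  X <- cbind("(Intercept)" = rep(1, nrow(sheet)),
             group_case = as.numeric(sheet$group == "case"))
  if (include_age) X <- cbind(X, age_years = sheet$age_years)
  if (include_sex) X <- cbind(X, sex_M = as.numeric(sheet$sex == "M"))
  if (!is.null(cell_covariates)) {
    idx <- match(sheet$sample_id, cell_covariates$sample_id)
    if (anyNA(idx)) abort("cell proportions missing for some modeled samples")
    cc <- as.matrix(cell_covariates[idx, setdiff(names(cell_covariates), "sample_id")])
    X <- cbind(X, cc)
  }
  if (!is.null(clock_residuals)) {
    idx <- match(sheet$sample_id, clock_residuals$sample_id)
    if (anyNA(idx)) abort("clock residuals missing for some modeled samples")
    X <- cbind(X, dnam_age_residual = clock_residuals$residual[idx])
  }
  rownames(X) <- sheet$sample_id
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  X
}

#' Fit per-CpG linear models
#'
#' Ordinary least squares per probe on the beta scale (via limma's
#' vectorised fitter), extracting the case/control coefficient. Probes
#' with missing values are fitted on complete cases with correspondingly
#' reduced residual df; probes with no residual df or an undefined
#' residual SD are flagged (`ok = FALSE`) and excluded from variance
#' moderation.
#'
#' @param beta Beta tibble containing every design sample.
#' @param design Design matrix from [build_design()].
#' @param coef Name of the effect column (default `"group_case"`).
#' @return Tibble per probe: `probe_id`, `coef`, `sigma`, `df_residual`,
#'   `stdev_unscaled`, `ok`.
#' @export
fit_linear_models <- function(beta, design, coef = "group_case") {
  validate_beta(beta)
  if (!coef %in% colnames(design)) {
    abort(paste0("design has no '", coef, "' column"))
  }
  m <- beta_to_matrix(beta)
  absent <- setdiff(rownames(design), colnames(m))
  if (length(absent) > 0) {
    abort(paste0("design samples missing from beta matrix: ",
                 paste(absent, collapse = ", ")))
  }
  m <- m[, rownames(design), drop = FALSE]
  if (ncol(m) <= ncol(design)) {
    abort("need more samples than design columns")
  }
  fit <- limma::lmFit(m, design)
  est <- unname(fit$coefficients[, coef])
  su <- unname(fit$stdev.unscaled[, coef])
  tibble(
    probe_id = rownames(m),
    coef = est,
    sigma = unname(fit$sigma),
    df_residual = unname(fit$df.residual),
    stdev_unscaled = su,
    ok = unname(fit$df.residual) > 0 & is.finite(unname(fit$sigma)) &
      is.finite(est)
  )
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks per-probe residual variances toward a common prior:
#' `s2_post = (d0 * s0^2 + df * s^2) / (d0 + df)`, with the moderated
#' statistic `t = coef / (sqrt(s2_post) * stdev_unscaled)` referred to a
#' t-distribution on `d0 + df` degrees of freedom (two-sided). The prior
#' `(d0, s0^2)` is estimated by the method of moments on the log
#' variances (via [limma::fitFDist()]); probes with zero variance are
#' excluded from that estimation. `d0 = 0` disables moderation (ordinary
#' t on `df` df); `d0 = Inf` fixes every posterior variance at `s0^2`
#' (normal reference).
#'
#' @param fits Tibble from [fit_linear_models()].
#' @param d0 Prior degrees of freedom; `NULL` (default) estimates `d0` and
#'   `s0^2` from the data.
#' @param s0_sq Prior variance, required when `d0 = Inf` is supplied
#'   without data estimation; otherwise estimated.
#' @return `fits` with columns `s2_post`, `moderated_t`, `df_total`,
#'   `p_value` added; attributes `d0` and `s0_sq` carry the prior.
#' @export
moderate_variances <- function(fits, d0 = NULL, s0_sq = NULL) {
  usable <- fits$ok & fits$df_residual > 0
  if (!any(usable)) abort("no probes with positive residual df")
  est_set <- usable & fits$sigma > 0
  if (is.null(d0) || (is.infinite(d0) && is.null(s0_sq)) ||
      (!is.null(d0) && d0 > 0 && is.null(s0_sq))) {
    if (sum(est_set) < 10) {
      abort("need >= 10 probes with positive variance to estimate the prior")
    }
    fd <- limma::fitFDist(fits$sigma[est_set]^2, df1 = fits$df_residual[est_set])
    if (is.null(d0)) d0 <- fd$df2
    if (is.null(s0_sq)) s0_sq <- fd$scale
  }
  if (d0 < 0) abort("d0 must be >= 0")

  s2 <- fits$sigma^2
  df <- fits$df_residual
  if (d0 == 0) {
    s2_post <- s2
    df_total <- df
    s0_sq <- s0_sq %||% NA_real_
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  tstat <- fits$coef / (sqrt(s2_post) * fits$stdev_unscaled)
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!usable | !is.finite(tstat)] <- NA_real_
  out <- dplyr::mutate(fits, s2_post = s2_post, moderated_t = tstat,
                       df_total = df_total, p_value = p)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after input
#' validation). Missing p-values stay missing.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Group mean methylation difference per CpG
#'
#' `delta_beta = mean(beta | discovery cases) - mean(beta | discovery
#' controls)`, skipping missing values within each group. Probes missing
#' in an entire group get `NA` with a warning and are excluded from
#' signature selection.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param roles Pair of roles defining the two groups (case role first).
#' @return Tibble: `probe_id`, `delta_beta`.
#' @export
delta_beta <- function(beta, sheet,
                       roles = c("discovery_case", "discovery_control")) {
  sheet <- validate_sample_sheet(sheet)
  m <- beta_to_matrix(beta)
  cases <- intersect(sheet$sample_id[sheet$role == roles[1]], colnames(m))
  ctrls <- intersect(sheet$sample_id[sheet$role == roles[2]], colnames(m))
  if (length(cases) == 0 || length(ctrls) == 0) {
    abort("both groups must be nonempty")
  }
  db <- rowMeans(m[, cases, drop = FALSE], na.rm = TRUE) -
    rowMeans(m[, ctrls, drop = FALSE], na.rm = TRUE)
  db[!is.finite(db)] <- NA_real_
  if (anyNA(db)) {
    warn(paste0(sum(is.na(db)), " probe(s) missing in an entire group; delta_beta set NA"))
  }
  tibble(probe_id = rownames(m), delta_beta = unname(db))
}

#' Covariate-adjusted differential methylation
#'
#' One-call wrapper over [build_design()], [fit_linear_models()],
#' [moderate_variances()], [bh_adjust()] and [delta_beta()]: fits the
#' moderated per-CpG model on the discovery samples and returns a result
#' object holding the full per-CpG table (`coef`, `delta_beta`, `sigma`,
#' `df_residual`, `moderated_t`, `p_value`, `q_value`, `direction`) and
#' the moderation prior. Use [select_signature()] to apply the dual
#' FDR / effect-size thresholds.
#'
#' @inheritParams build_design
#' @param beta Beta tibble (post-QC).
#' @param d0 Prior df override passed to [moderate_variances()].
#' @return An object of class `episig_diffmeth`.
#' @export
run_diffmeth <- function(beta, sheet, cell_covariates = NULL,
                         clock_residuals = NULL, include_age = TRUE,
                         include_sex = TRUE, d0 = NULL) {
  design <- build_design(sheet, cell_covariates, clock_residuals,
                         include_age, include_sex)
  fits <- fit_linear_models(beta, design)
  mod <- moderate_variances(fits, d0 = d0)
  db <- delta_beta(beta, sheet)
  tab <- mod |>
    dplyr::left_join(db, by = "probe_id") |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  direction = dplyr::if_else(.data$delta_beta > 0,
                                             "hyper", "hypo")) |>
    dplyr::select("probe_id", "coef", "delta_beta", "sigma", "df_residual",
                  "moderated_t", "p_value", "q_value", "direction", "ok")
  structure(list(table = tab,
                 d0 = attr(mod, "d0"),
                 s0_sq = attr(mod, "s0_sq"),
                 design_columns = colnames(design),
                 n_samples = nrow(design)),
            class = "episig_diffmeth")
}

#' @export
print.episig_diffmeth <- function(x, ...) {
  cat("Differential methylation fit:", nrow(x$table), "probes,",
      x$n_samples, "samples\n")
  cat("design:", paste(x$design_columns, collapse = " + "), "\n")
  cat(sprintf("moderation prior: d0 = %.3g, s0^2 = %.3g\n", x$d0, x$s0_sq))
  invisible(x)
}

#' Select the episignature
#'
#' Dual-threshold selection: CpGs with `q_value < q_max` AND
#' `|delta_beta| > min_abs_delta` (both strict). Sorted by `q_value`, then
#' decreasing `|delta_beta|`, ties broken by probe id so the order is
#' deterministic. An empty signature is allowed (with a warning).
#'
#' @param result An `episig_diffmeth` or its per-CpG tibble.
#' @param q_max FDR threshold (default 0.05).
#' @param min_abs_delta Effect-size threshold on the beta scale
#'   (default 0.10).
#' @return Tibble of selected rows.
#' @export
select_signature <- function(result, q_max = 0.05, min_abs_delta = 0.10) {
  tab <- if (inherits(result, "episig_diffmeth")) result$table else result
  sig <- tab |>
    dplyr::filter(!is.na(.data$q_value), !is.na(.data$delta_beta),
                  .data$q_value < q_max,
                  abs(.data$delta_beta) > min_abs_delta) |>
    dplyr::arrange(.data$q_value, dplyr::desc(abs(.data$delta_beta)),
                   .data$probe_id)
  if (nrow(sig) == 0) warn("empty signature at these thresholds")
  sig
}

#' Hyper/hypomethylated fractions of a signature
#'
#' @param signature Tibble with a `delta_beta` column.
#' @return One-row tibble: `n`, `fraction_hyper`, `fraction_hypo`.
#' @export
direction_summary <- function(signature) {
  if (nrow(signature) == 0) abort("signature is empty")
  hyper <- mean(signature$delta_beta > 0)
  tibble(n = nrow(signature), fraction_hyper = hyper,
         fraction_hypo = 1 - hyper)
}
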