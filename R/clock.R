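#' Epigenetic clock age transform
#'
#' The piecewise age transform used by weighted-CpG epigenetic clocks:
#' logarithmic in childhood, linear in adulthood, continuous and strictly
#' increasing with a fixed point at `adult_age`:
#' `log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, else
#' `(age - adult_age) / (adult_age + 1)`.
#'
#' @param age Chronological age in years (> -1); vectorized.
#' @param adult_age Knot of the transform in years (default 20).
#' @return Transformed age(s).
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(age <= -1)) abort("age must be > -1")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @param x Transformed age value(s).
#' @export
inverse_transform_age <- function(x, adult_age = 20) {
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Construct a clock model
#'
#' @param intercept Intercept of the linear predictor on the transformed
#'   age scale.
#' @param coefficients Named numeric vector of per-CpG weights.
#' @param adult_age Transform knot in years.
#' @return An object of class `episig_clock`.
#' @export
clock_model <- function(intercept, coefficients, adult_age = 20) {
  if (length(coefficients) < 1) abort("clock needs >= 1 CpG coefficient")
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    abort("clock coefficients must have unique CpG names")
  }
  if (adult_age <= -1) abort("adult_age must be > -1")
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 adult_age = adult_age),
            class = "episig_clock")
}

#' Read / write a clock coefficient file
#'
#' CSV with columns `cpg`, `weight`; the rows `(Intercept)` and
#' `(AdultAge)` carry the intercept and the transform knot.
#'
#' @param path CSV path.
#' @return [read_clock()]: an `episig_clock`; [write_clock()]: `path`,
#'   invisibly.
#' @export
read_clock <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cpg", "weight") %in% names(tbl))) {
    abort("clock file needs columns cpg, weight")
  }
  ic <- tbl$weight[tbl$cpg == "(Intercept)"]
  aa <- tbl$weight[tbl$cpg == "(AdultAge)"]
  cf <- tbl[!tbl$cpg %in% c("(Intercept)", "(AdultAge)"), ]
  clock_model(intercept = if (length(ic)) ic[1] else 0,
              coefficients = setNames(cf$weight, cf$cpg),
              adult_age = if (length(aa)) aa[1] else 20)
}

#' @rdname read_clock
#' @param clock An `episig_clock`.
#' @export
write_clock <- function(clock, path) {
  tbl <- tibble(cpg = c("(Intercept)", "(AdultAge)", names(clock$coefficients)),
                weight = c(clock$intercept, clock$adult_age,
                           unname(clock$coefficients)))
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Predict DNA methylation age
#'
#' Applies a weighted-CpG clock: the linear predictor
#' `intercept + sum(w_i * beta_i)` is mapped back to years through
#' [inverse_transform_age()]. Clock CpGs missing from the matrix (or
#' missing for individual samples) are imputed with the cohort mean at
#' that CpG, with a warning, as long as no more than `max_missing` of the
#' clock CpGs are absent; beyond that the prediction errors out.
#'
#' @param beta Beta tibble.
#' @param clock An `episig_clock`.
#' @param max_missing Maximum tolerated fraction of absent clock CpGs
#'   (default 0.05).
#' @return Tibble with `sample_id` and `dnam_age` (years).
#' @export
predict_dnam_age <- function(beta, clock, max_missing = 0.05) {
  stopifnot(inherits(clock, "episig_clock"))
  validate_beta(beta)
  cpgs <- names(clock$coefficients)
  absent <- setdiff(cpgs, beta$probe_id)
  if (length(absent) > length(cpgs) * max_missing) {
    abort(paste0(length(absent), " of ", length(cpgs),
                 " clock CpGs missing from beta matrix (> ",
                 format(100 * max_missing), "%)"))
  }
  m <- beta_to_matrix(beta)
  present <- intersect(cpgs, rownames(m))
  X <- m[present, , drop = FALSE]
  if (anyNA(X)) {
    rm_ <- rowMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- rm_[idx[, 1]]
    warn("missing clock CpG values imputed with the cohort mean")
  }
  if (length(absent) > 0) {
    warn(paste0("clock CpGs absent from matrix treated as cohort-mean 0.5: ",
                paste(absent, collapse = ", ")))
    X <- rbind(X, matrix(0.5, length(absent), ncol(X),
                         dimnames = list(absent, colnames(X))))
  }
  lp <- clock$intercept + drop(crossprod(X[cpgs, , drop = FALSE],
                                         clock$coefficients[cpgs]))
  tibble(sample_id = colnames(m),
         dnam_age = unname(inverse_transform_age(lp, clock$adult_age)))
}

#' Age acceleration and clock residuals
#'
#' `age_acceleration()` joins DNAm ages to the sample sheet and returns,
#' per sample, the chronological age, the acceleration
#' `dnam_age - age_years`, and the residual from an ordinary least-squares
#' regression of DNAm age on chronological age fitted over `fitting_roles`
#' samples (residuals are reported for all samples relative to that fit).
#'
#' @param dnam_ages Tibble from [predict_dnam_age()].
#' @param sheet Sample sheet with `age_years` for every scored sample.
#' @param fitting_roles Roles defining the regression fitting set; default
#'   is all samples entering the differential model (discovery cases and
#'   controls).
#' @return Tibble: `sample_id`, `group`, `role`, `chrono_age`, `dnam_age`,
#'   `acceleration`, `residual`.
#' @export
age_acceleration <- function(dnam_ages, sheet,
                             fitting_roles = c("discovery_case",
                                               "discovery_control")) {
  sheet <- validate_sample_sheet(sheet)
  tbl <- dplyr::inner_join(dnam_ages, sheet, by = "sample_id")
  if (nrow(tbl) < nrow(dnam_ages)) {
    abort("chronological age missing for some scored samples")
  }
  fit_set <- tbl$role %in% fitting_roles
  if (sum(fit_set) < 3) abort("need >= 3 samples in the residual fitting set")
  if (sd(tbl$age_years[fit_set]) == 0) {
    abort("chronological ages constant in fitting set; residual fit undefined")
  }
  fit <- lm(dnam_age ~ age_years, data = tbl[fit_set, ])
  tibble(sample_id = tbl$sample_id,
         group = tbl$group,
         role = tbl$role,
         chrono_age = tbl$age_years,
         dnam_age = tbl$dnam_age,
         acceleration = tbl$dnam_age - tbl$age_years,
         residual = tbl$dnam_age - unname(predict(fit, tbl)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of `x` vs `y`; exact when there are at most 25
#' non-zero differences and no ties, normal approximation with continuity
#' correction otherwise. If every difference is zero the test is
#' degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `statistic` (V), `p_value`, `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warn("all paired differences are zero; returning p = 1")
    return(tibble(statistic = NA_real_, p_value = 1, method = "degenerate"))
  }
  if (length(nz) < 3) abort("need >= 3 non-zero paired differences")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test; exact when the smaller group has at
#' most 8 observations and there are no ties, normal approximation with
#' tie correction and continuity correction otherwise.
#'
#' @param x,y Numeric vectors (independent groups).
#' @return One-row tibble: `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal approximation")
}
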