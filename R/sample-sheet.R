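#' Read a sample sheet
#'
#' The sample sheet carries per-sample metadata: `sample_id`, `group`
#' (`case` / `control`), `role` (`discovery_case`, `discovery_control`,
#' `validation_case`, `validation_control`, or `test`), `sex` (`F` / `M`)
#' and `age_years` (non-negative, fractional ages allowed -- a 2-day-old is
#' 2/365.25). Only `discovery_*` samples ever enter model fitting.
#'
#' @param path CSV file with the columns above.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  tbl <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(sample_id = "c", group = "c", role = "c",
                            sex = "c",  # "F" must not parse as FALSE
                            age_years = "d", .default = readr::col_guess())
  )
  validate_sample_sheet(tbl)
}

sheet_roles <- c("discovery_case", "discovery_control",
                 "validation_case", "validation_control", "test")

#' Validate a sample sheet
#'
#' @param sheet Data frame with sample-sheet columns.
#' @return The sheet as a tibble, invisibly usable downstream.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "role", "sex", "age_years")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing columns: ", paste(miss, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                       collapse = ", ")))
  }
  bad_group <- setdiff(unique(sheet$group), c("case", "control"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown group labels: ", paste(bad_group, collapse = ", ")))
  }
  bad_role <- setdiff(unique(sheet$role), sheet_roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown roles: ", paste(bad_role, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(sheet$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex codes: ", paste(bad_sex, collapse = ", ")))
  }
  if (any(is.na(sheet$age_years)) || any(sheet$age_years < 0)) {
    abort("age_years must be non-negative and non-missing")
  }
  sheet
}

#' Summarize a cohort
#'
#' Counts and age summary (mean, sample SD with n-1 denominator, range)
#' for the samples matching `roles`. With a single sample the SD is
#' undefined and reported as 0 with `sd_undefined = TRUE`.
#'
#' @param sheet Sample sheet.
#' @param roles Character vector of roles to keep; `NULL` keeps all rows.
#' @return One-row tibble: `n`, `n_female`, `n_male`, `mean_age`, `sd_age`,
#'   `min_age`, `max_age`, `sd_undefined`.
#' @export
summarize_cohort <- function(sheet, roles = NULL) {
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(roles)) sheet <- dplyr::filter(sheet, .data$role %in% roles)
  if (nrow(sheet) == 0) abort("no samples left after role filter")
  n <- nrow(sheet)
  tibble(
    n = n,
    n_female = sum(sheet$sex == "F"),
    n_male = sum(sheet$sex == "M"),
    mean_age = mean(sheet$age_years),
    sd_age = if (n > 1) sd(sheet$age_years) else 0,
    min_age = min(sheet$age_years),
    max_age = max(sheet$age_years),
    sd_undefined = n == 1
  )
}
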