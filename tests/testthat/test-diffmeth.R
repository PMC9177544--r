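test_that("design matrix has the documented columns and rank checks", {
  sim <- small_sim(seed = 2)
  props <- estimate_cell_proportions(sim$beta, sim$cell_reference)
  acc <- age_acceleration(predict_dnam_age(sim$beta, sim$clock), sim$sheet)
  X <- build_design(sim$sheet, covariate_block(props), acc)
  # intercept + group + age + sex + 5 cell proportions + clock residual
  expect_equal(ncol(X), 10)
  expect_equal(nrow(X), 34)
  expect_setequal(unique(X[, "group_case"]), c(0, 1))

  # covariates disabled -> intercept + group only
  X2 <- build_design(sim$sheet, include_age = FALSE, include_sex = FALSE)
  expect_identical(colnames(X2), c("(Intercept)", "group_case"))

  # single-sex cohort makes the sex column constant -> named rank error
  sheet <- tiny_sheet()
  sheet$sex <- "M"
  expect_error(build_design(sheet), "sex_M")
})

test_that("per-CpG fits equal closed-form OLS", {
  beta <- tiny_beta()
  sheet <- tiny_sheet()
  X <- build_design(sheet, include_age = FALSE, include_sex = FALSE)
  fits <- fit_linear_models(beta, X)
  m <- beta_to_matrix(beta)
  # two-group model: coefficient is the difference of group means
  expect_equal(fits$coef,
               unname(rowMeans(m[, 1:3]) - rowMeans(m[, 4:6])),
               tolerance = 1e-12)
  expect_equal(fits$df_residual, rep(4, 5))

  # with a covariate: must match stats::lm probe by probe
  X3 <- build_design(sheet, include_sex = FALSE)
  fits3 <- fit_linear_models(beta, X3)
  for (i in 1:5) {
    lmfit <- lm(m[i, ] ~ X3[, "group_case"] + X3[, "age_years"])
    expect_equal(fits3$coef[i], unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fits3$sigma[i], summary(lmfit)$sigma, tolerance = 1e-10)
  }

  # constant probe: zero residual variance, flagged not ok for moderation
  cbeta <- beta
  cbeta[1, -1] <- as.list(rep(0.5, 6))
  cfits <- fit_linear_models(cbeta, X)
  expect_equal(cfits$coef[1], 0)
  expect_equal(cfits$sigma[1], 0)
})

test_that("missing values reduce df and are fitted on complete cases", {
  beta <- tiny_beta()
  beta$A[2] <- NA
  X <- build_design(tiny_sheet(), include_age = FALSE, include_sex = FALSE)
  fits <- fit_linear_models(beta, X)
  expect_equal(fits$df_residual[2], 3)
  m <- beta_to_matrix(beta)
  expect_equal(fits$coef[2],
               mean(m[2, 2:3]) - mean(m[2, 4:6]), tolerance = 1e-12)
})

test_that("moderation limiting cases and agreement with the reference EB fit", {
  sim <- small_sim(seed = 4)
  X <- build_design(sim$sheet)
  beta <- sim$beta[1:500, ]
  fits <- fit_linear_models(beta, X)

  # d0 = 0 disables moderation: ordinary t
  m0 <- moderate_variances(fits, d0 = 0)
  expect_equal(m0$moderated_t, fits$coef / (fits$sigma * fits$stdev_unscaled),
               tolerance = 1e-12)
  expect_equal(m0$df_total, fits$df_residual)

  # d0 = Inf pins the posterior variance at s0^2
  mi <- moderate_variances(fits, d0 = Inf, s0_sq = 0.01)
  expect_equal(mi$moderated_t, fits$coef / (0.1 * fits$stdev_unscaled),
               tolerance = 1e-12)

  # estimated prior: matches limma's eBayes moderated t and p
  mod <- moderate_variances(fits)
  lfit <- limma::lmFit(beta_to_matrix(beta)[, rownames(X)], X)
  eb <- limma::eBayes(lfit)
  expect_equal(attr(mod, "d0"), eb$df.prior, tolerance = 1e-8)
  expect_equal(attr(mod, "s0_sq"), eb$s2.prior, tolerance = 1e-8)
  expect_equal(mod$moderated_t, unname(eb$t[, "group_case"]),
               tolerance = 1e-8)
  expect_equal(mod$p_value, unname(eb$p.value[, "group_case"]),
               tolerance = 1e-8)
})

test_that("null data give uniform p-values and calibrated type-I error", {
  set.seed(101)
  n <- 20
  m <- matrix(rnorm(10000 * n, mean = 0.5, sd = 0.05), 10000, n,
              dimnames = list(sprintf("cg%05d", 1:10000),
                              sprintf("s%02d", 1:n)))
  sheet <- tibble::tibble(
    sample_id = colnames(m),
    group = rep(c("case", "control"), each = n / 2),
    role = rep(c("discovery_case", "discovery_control"), each = n / 2),
    sex = rep_len(c("F", "M"), n),
    age_years = runif(n, 4, 30)
  )
  X <- build_design(sheet, include_age = FALSE, include_sex = FALSE)
  mod <- moderate_variances(fit_linear_models(matrix_to_beta(m), X))
  expect_equal(mean(mod$p_value < 0.05), 0.05, tolerance = 0.01)
  ks <- stats::ks.test(mod$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
  # BH controls the FDR: essentially nothing passes q < 0.05 under the null
  q <- bh_adjust(mod$p_value)
  expect_lt(mean(q < 0.05), 1e-3)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.0123), 0.0123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_along(p), function(i) {
      min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
    }, 1)
  }
  set.seed(7)
  for (rep in 1:5) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))          # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("delta_beta is the difference of group means with missing handling", {
  beta <- tiny_beta()
  sheet <- tiny_sheet()
  db <- delta_beta(beta, sheet)
  m <- beta_to_matrix(beta)
  expect_equal(db$delta_beta, unname(rowMeans(m[, 1:3]) - rowMeans(m[, 4:6])))

  b2 <- beta
  b2[1, c("A", "B", "C")] <- as.list(c(NA_real_, NA_real_, NA_real_))
  expect_warning(db2 <- delta_beta(b2, sheet), "entire group")
  expect_true(is.na(db2$delta_beta[1]))
  expect_equal(db2$delta_beta[-1], db$delta_beta[-1])
})

test_that("signature selection applies strict dual thresholds deterministically", {
  tab <- tibble::tibble(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE"),
    delta_beta = c(0.15, 0.10, -0.25, 0.12, -0.12),
    q_value = c(0.04, 0.04, 0.049, 0.05, 0.04)
  )
  sig <- select_signature(tab)
  # cgB fails |delta| > 0.10 (exactly 0.10); cgD fails q < 0.05 (exactly 0.05)
  expect_setequal(sig$probe_id, c("cgA", "cgC", "cgE"))
  # sorted by q then |delta| descending, probe id as final tie-break
  expect_identical(sig$probe_id, c("cgA", "cgE", "cgC"))

  expect_warning(empty <- select_signature(tab, q_max = 1e-6), "empty")
  expect_equal(nrow(empty), 0)

  ds <- direction_summary(sig)
  expect_equal(ds$fraction_hyper + ds$fraction_hypo, 1)
  expect_equal(ds$fraction_hyper, 1 / 3)
  expect_error(direction_summary(empty), "empty")
})

test_that("signature discovery is invariant to probe and sample order", {
  sim <- small_sim(seed = 6, delta_range = c(0.15, 0.15))
  qc <- filter_probes(sim$beta, sim$manifest)
  dm <- run_diffmeth(qc$beta, sim$sheet)
  sig <- select_signature(dm)

  set.seed(99)
  beta_perm <- qc$beta[sample(nrow(qc$beta)),
                       c(1, 1 + sample(ncol(qc$beta) - 1))]
  dm2 <- run_diffmeth(beta_perm, sim$sheet)
  sig2 <- select_signature(dm2)
  expect_identical(sig$probe_id, sig2$probe_id)
  expect_equal(sig$q_value, sig2$q_value, tolerance = 1e-12)
})
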