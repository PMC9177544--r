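test_that("age transform: fixed point, linear branch, closed form, inverse", {
  expect_equal(transform_age(20, 20), 0)
  expect_equal(transform_age(41, 20), 1)           # (41 - 20) / 21
  expect_equal(transform_age(0, 20), -log(21))     # about -3.0445
  expect_equal(inverse_transform_age(0, 20), 20)
  expect_equal(inverse_transform_age(1, 20), 41)
  expect_error(transform_age(-1), "age")

  grid <- seq(0, 90, by = 0.25)
  expect_equal(inverse_transform_age(transform_age(grid)), grid,
               tolerance = 1e-10)
  # continuity and monotonicity across the knot
  vals <- transform_age(grid)
  expect_true(all(diff(vals) > 0))
  expect_lt(abs(transform_age(20 + 1e-9) - transform_age(20 - 1e-9)), 1e-8)
})

test_that("clock prediction inverts a constructed linear predictor", {
  cpgs <- paste0("cg", 1:4)
  w <- c(0.5, 0.25, 1, 0.75)
  clock <- clock_model(intercept = 0, coefficients = setNames(w, cpgs))

  # choose betas with linear predictor = transform_age(35)
  target <- transform_age(35)
  b <- rep(0.4, 4)
  b[3] <- (target - sum(w[-3] * b[-3])) / w[3]
  stopifnot(b[3] >= 0, b[3] <= 1)
  beta <- matrix_to_beta(matrix(b, 4, 2, dimnames = list(cpgs, c("s1", "s2"))))
  out <- predict_dnam_age(beta, clock)
  expect_equal(out$dnam_age, c(35, 35), tolerance = 1e-8)

  # all-zero weights, zero intercept -> adult_age for every sample
  zero <- clock_model(0, setNames(rep(0, 4), cpgs), adult_age = 20)
  expect_equal(predict_dnam_age(beta, zero)$dnam_age, c(20, 20))
})

test_that("missing clock CpGs follow the 5% policy", {
  cpgs <- paste0("cg", 1:20)
  clock <- clock_model(0, setNames(rep(0.1, 20), cpgs))
  m <- matrix(0.5, 20, 3, dimnames = list(cpgs, c("a", "b", "c")))

  # one of twenty absent (5%) -> imputed with a warning
  beta19 <- matrix_to_beta(m[-1, ])
  expect_warning(out <- predict_dnam_age(beta19, clock), "absent")
  expect_equal(nrow(out), 3)

  # two of twenty absent (10%) -> error
  beta18 <- matrix_to_beta(m[-(1:2), ])
  expect_error(predict_dnam_age(beta18, clock), "clock CpGs missing")

  # missing cells (not whole probes) imputed with cohort mean
  m2 <- m
  m2[1, 1] <- NA
  expect_warning(predict_dnam_age(matrix_to_beta(m2), clock), "imputed")
})

test_that("acceleration is the elementwise difference and residuals match closed form", {
  sheet <- tiny_sheet()
  dnam <- tibble::tibble(sample_id = sheet$sample_id,
                         dnam_age = 2 * sheet$age_years)
  res <- age_acceleration(dnam, sheet)
  expect_equal(res$acceleration, res$dnam_age - res$chrono_age)
  # dnam exactly 2 * chrono -> perfect fit, all residuals zero
  expect_equal(res$residual, rep(0, 6), tolerance = 1e-10)

  # hand-solved 3-point least squares: chrono (1,2,3), dnam (2,3,5)
  # slope 1.5, intercept 1/3 -> residuals (1/6, -1/3, 1/6)
  sheet3 <- tibble::tibble(sample_id = c("x", "y", "z"),
                           group = c("case", "control", "control"),
                           role = c("discovery_case", "discovery_control",
                                    "discovery_control"),
                           sex = c("F", "M", "F"),
                           age_years = c(1, 2, 3))
  dnam3 <- tibble::tibble(sample_id = c("x", "y", "z"),
                          dnam_age = c(2, 3, 5))
  r3 <- age_acceleration(dnam3, sheet3)
  expect_equal(r3$residual, c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)
  # one point above the fitted line has a positive residual
  expect_gt(r3$residual[1], 0)

  const <- sheet3
  const$age_years <- c(5, 5, 5)
  expect_error(age_acceleration(dnam3, const), "constant")
})

test_that("planted acceleration is recovered from simulated clock CpGs", {
  sim <- small_sim(seed = 5)
  ages <- predict_dnam_age(sim$beta, sim$clock)
  acc <- age_acceleration(ages, sim$sheet)
  truth <- sim$truth$ages
  err <- acc$acceleration - truth$acceleration[match(acc$sample_id,
                                                     truth$sample_id)]
  expect_lt(max(abs(err)), 0.5)
  case_mean <- mean(acc$acceleration[acc$group == "case"])
  true_mean <- mean(truth$acceleration[sim$sheet$group == "case"])
  expect_equal(case_mean, true_mean, tolerance = 0.1)
})

test_that("paired Wilcoxon matches exact enumeration", {
  # all-positive differences {1..5}: only the all-positive and all-negative
  # sign patterns are as extreme, p = 2/2^5
  r <- paired_wilcoxon(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$p_value, 2 / 32)
  expect_identical(r$method, "exact")

  expect_warning(r0 <- paired_wilcoxon(1:4, 1:4), "zero")
  expect_equal(r0$p_value, 1)

  # brute-force enumeration over all sign assignments at n = 6
  set.seed(8)
  x <- round(rnorm(6), 2)
  y <- round(rnorm(6), 2)
  d <- x - y
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  v_all <- as.matrix(signs) %*% rk
  p_exact <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(paired_wilcoxon(x, y)$p_value, p_exact)
})

test_that("Mann-Whitney U matches exact enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)  # no x exceeds any y
  expect_equal(r$p_value, 1 / 3)        # 2 of 6 orderings as extreme

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # enumeration of all C(8,4) group assignments at n = m = 4
  set.seed(9)
  pool <- round(rnorm(8), 3)
  stopifnot(!any(duplicated(pool)))
  x <- pool[1:4]; y <- pool[5:8]
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(8, 4)
  u_all <- apply(combs, 2, function(i) u_of(pool[i], pool[-i]))
  p_exact <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(mann_whitney_u(x, y)$p_value, p_exact)
})
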