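train_ids <- function(sheet) {
  sheet$sample_id[sheet$role %in% c("discovery_case", "discovery_control")]
}

test_that("pruning removes duplicates, keeps independent features, asserts its contract", {
  set.seed(21)
  n <- 20
  base <- rnorm(n)
  m <- rbind(f1 = base,
             f2 = base,                      # exact duplicate of f1
             f3 = rnorm(n),
             f4 = rnorm(n))
  m <- (m - min(m)) / (max(m) - min(m))      # into [0, 1]
  colnames(m) <- sprintf("s%02d", 1:n)
  beta <- matrix_to_beta(m)

  pr <- prune_correlated(beta, rownames(m), colnames(m))
  expect_equal(nrow(pr$removed), 1)
  expect_setequal(pr$removed$probe_id, "f2")  # tie broken by larger id
  expect_setequal(pr$kept, c("f1", "f3", "f4"))

  cm <- abs(cor(t(beta_to_matrix(beta)[pr$kept, ])))
  diag(cm) <- 0
  expect_lt(max(cm), pr$cutoff)

  # mutually independent features are all kept
  set.seed(22)
  ind <- matrix(runif(6 * 50), 6, 50,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:50)))
  pr2 <- prune_correlated(matrix_to_beta(ind), paste0("g", 1:6),
                          paste0("s", 1:50))
  expect_length(pr2$kept, 6)
  expect_equal(nrow(pr2$removed), 0)
})

test_that("pruning follows the greedy worst-pair rule on a constructed 4-feature case", {
  # construct features where (a,b) is the worst pair and b has the larger
  # mean absolute correlation (b also correlates with c)
  set.seed(23)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- z1
  b <- z1 + 0.1 * z2 + rnorm(n, sd = 0.05)    # |r(a,b)| ~ 0.99, worst pair
  c <- z2 + 0.3 * z1                          # correlates more with b than a
  d <- rnorm(n)
  m <- rbind(a = a, b = b, c = c, d = d)
  m <- (m - min(m)) / (max(m) - min(m))
  colnames(m) <- sprintf("s%03d", 1:n)
  beta <- matrix_to_beta(m)

  cm <- abs(cor(t(m[c("a", "b", "c", "d"), ])))
  diag(cm) <- 0
  stopifnot(max(cm) == cm["a", "b"], cm["a", "b"] >= 0.9,
            mean(cm["b", ]) > mean(cm["a", ]))
  # greedy oracle, executed step by step on the frozen correlation matrix
  expected_removed <- "b"
  stopifnot(max(cm[c("a", "c", "d"), c("a", "c", "d")]) < 0.9)

  pr <- prune_correlated(beta, c("a", "b", "c", "d"), colnames(m))
  expect_identical(pr$removed$probe_id, expected_removed)
  expect_setequal(pr$kept, c("a", "c", "d"))
  expect_error(prune_correlated(beta, c("a", "b"), "s001"), ">= 2 training")
})

test_that("training is deterministic and separates planted cohorts", {
  sim <- small_sim(seed = 31, delta_range = c(0.15, 0.15))
  qc <- filter_probes(sim$beta, sim$manifest)
  dm <- run_diffmeth(qc$beta, sim$sheet)
  sig <- select_signature(dm)
  expect_gt(nrow(sig), 1)
  pr <- prune_correlated(sim$beta, sig$probe_id, train_ids(sim$sheet))
  mod <- train_classifier(sim$beta, sim$sheet, pr, seed = 5)

  # training accuracy 1.0 on the linearly separable planted cohorts
  train_beta <- sim$beta[, c("probe_id", train_ids(sim$sheet))]
  sc <- score_samples(mod, train_beta)
  grp <- sim$sheet$group[match(sc$sample_id, sim$sheet$sample_id)]
  expect_true(all(sc$call[grp == "case"] == "high"))
  expect_true(all(sc$call[grp == "control"] == "low"))

  # same data + same seed -> byte-identical serialized models
  mod2 <- train_classifier(sim$beta, sim$sheet, pr, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_classifier(mod, f1)
  write_classifier(mod2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # single-class training set is rejected
  cases_only <- dplyr::filter(sim$sheet, group == "case")
  expect_error(train_classifier(sim$beta, cases_only, pr), "both classes")
})

test_that("JSON round trip scores identically to the in-memory model", {
  sim <- small_sim(seed = 32, delta_range = c(0.15, 0.15))
  qc <- filter_probes(sim$beta, sim$manifest)
  sig <- select_signature(run_diffmeth(qc$beta, sim$sheet))
  pr <- prune_correlated(sim$beta, sig$probe_id, train_ids(sim$sheet))
  mod <- train_classifier(sim$beta, sim$sheet, pr, seed = 6)

  tst <- simulate_test_samples(sim, "case_like", 5, seed = 33)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(mod, path)
  mod2 <- read_classifier(path)
  s1 <- score_samples(mod, tst$beta)
  s2 <- score_samples(mod2, tst$beta)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_true(all(s1$score > 0 & s1$score < 1))
})

test_that("scoring applies the missing-feature policy and order invariance", {
  sim <- small_sim(seed = 34, delta_range = c(0.15, 0.15))
  qc <- filter_probes(sim$beta, sim$manifest)
  sig <- select_signature(run_diffmeth(qc$beta, sim$sheet))
  pr <- prune_correlated(sim$beta, sig$probe_id, train_ids(sim$sheet))
  # keep several features for the missingness arithmetic
  feats <- head(sig$probe_id, 10)
  mod <- train_classifier(sim$beta, sim$sheet, feats, seed = 7)

  tst <- simulate_test_samples(sim, "control_like", 4, seed = 35)
  base <- score_samples(mod, tst$beta)

  # a sample missing 1 of 10 features (10%) is imputed with a warning
  b1 <- tst$beta
  b1[b1$probe_id == feats[1], 2] <- NA
  expect_warning(s1 <- score_samples(mod, b1), "imputed")
  expect_true(all(s1$scoreable))
  expect_equal(s1$n_missing[1], 1)

  # a sample missing 3 of 10 features (30% > 20%) is unscoreable
  b3 <- tst$beta
  for (f in feats[1:3]) b3[b3$probe_id == f, 2] <- NA
  s3 <- suppressWarnings(score_samples(mod, b3))
  expect_false(s3$scoreable[1])
  expect_true(is.na(s3$score[1]))
  expect_true(all(s3$scoreable[-1]))

  # probe and sample order do not change scores
  set.seed(36)
  shuf <- tst$beta[sample(nrow(tst$beta)), c(1, 1 + sample(4))]
  s_shuf <- score_samples(mod, shuf)
  expect_equal(dplyr::arrange(s_shuf, sample_id)$score,
               dplyr::arrange(base, sample_id)$score,
               tolerance = 1e-12)
})

test_that("a boundary score of exactly 0.5 is called low with a warning", {
  # degenerate calibration (A = B = 0) pins every probability at 0.5
  mod <- structure(list(
    features = c("f1", "f2"),
    center = c(f1 = 0.5, f2 = 0.5), scale = c(f1 = 0.1, f2 = 0.1),
    impute_means = c(f1 = 0.5, f2 = 0.5),
    kernel = "linear", cost = 1, gamma = 0.5,
    support_vectors = matrix(0, 1, 2), dual_coefs = 0, rho = 0,
    prob_a = 0, prob_b = 0, first_class = "case",
    weights = c(0, 0),
    classes = c("control", "case"), seed = 1L
  ), class = "episig_classifier")
  beta <- matrix_to_beta(matrix(c(0.4, 0.6), 2, 1,
                                dimnames = list(c("f1", "f2"), "s1")))
  expect_warning(sc <- score_samples(mod, beta), "0.5")
  expect_identical(sc$call, "low")
})

test_that("cohort evaluation reports sensitivity and specificity with ranges", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    score = c(0.9, 0.8, 0.3, 0.1, 0.2, 0.7),
    call = c("high", "high", "low", "low", "low", "high"),
    n_missing = 0L, scoreable = TRUE,
    cohort = c("val", "val", "val", "ctrl", "ctrl", "ctrl")
  )
  ev <- evaluate_cohorts(scores, c(val = "case", ctrl = "control"))
  expect_equal(ev$sensitivity[ev$cohort == "val"], 2 / 3)
  expect_equal(ev$specificity[ev$cohort == "ctrl"], 2 / 3)
  expect_equal(ev$min_score[ev$cohort == "val"], 0.3)
  expect_warning(evaluate_cohorts(scores, c(nope = "case")), "empty")
})
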