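#' Prune correlated signature CpGs
#'
#' Greedy removal of redundant features: while any pair of kept CpGs has
#' `|Pearson r| >= cutoff` over the training samples, the worst pair
#' (largest `|r|`, ties broken by probe-id order) is found and the member
#' with the larger mean absolute correlation to all other kept features is
#' removed (lexicographically larger probe id on a tie). On exit no kept
#' pair reaches the cutoff; this post-condition is re-asserted on every
#' run.
#'
#' @param beta Beta tibble restricted (or restrictable) to the signature
#'   CpGs.
#' @param features Character vector of signature probe ids.
#' @param samples Character vector of training sample ids (pruning must
#'   only see training data).
#' @param cutoff Absolute-correlation cutoff (default 0.90; a pair at
#'   exactly the cutoff is pruned).
#' @return List of class `episig_pruned`: `kept` (ordered probe ids),
#'   `removed` (tibble: `probe_id`, `paired_with`, `r`), `cutoff`.
#' @export
prune_correlated <- function(beta, features, samples, cutoff = 0.90) {
  validate_beta(beta)
  if (length(samples) < 2) abort("need >= 2 training samples to correlate")
  if (length(features) < 2) abort("need >= 2 features to prune")
  miss <- setdiff(features, beta$probe_id)
  if (length(miss) > 0) {
    abort(paste0("features absent from beta matrix: ",
                 paste(head(miss, 10), collapse = ", ")))
  }
  m <- beta_to_matrix(beta)[features, samples, drop = FALSE]
  # correlations over training samples; constant probes correlate as 0
  cm <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  acm <- abs(cm)

  kept <- sort(features)
  acm <- acm[kept, kept, drop = FALSE]
  removed <- list()
  while (length(kept) > 1 && max(acm) >= cutoff) {
    worst <- which(acm == max(acm), arr.ind = TRUE)
    # deterministic worst pair: first by row then column name order
    pair <- sort(c(rownames(acm)[worst[1, "row"]],
                   colnames(acm)[worst[1, "col"]]))
    mean_abs <- rowMeans(acm[pair, , drop = FALSE])
    drop_id <- if (mean_abs[pair[1]] > mean_abs[pair[2]]) pair[1]
      else if (mean_abs[pair[2]] > mean_abs[pair[1]]) pair[2]
      else pair[2]   # tie: remove the lexicographically larger id
    removed[[length(removed) + 1]] <- tibble(
      probe_id = drop_id,
      paired_with = setdiff(pair, drop_id),
      r = cm[pair[1], pair[2]]
    )
    kept <- setdiff(kept, drop_id)
    acm <- acm[kept, kept, drop = FALSE]
  }
  if (length(kept) > 1 && max(acm) >= cutoff) {
    abort("pruning post-condition violated")  # unreachable guard
  }
  structure(list(kept = kept,
                 removed = dplyr::bind_rows(removed),
                 cutoff = cutoff),
            class = "episig_pruned")
}

#' @export
print.episig_pruned <- function(x, ...) {
  cat("Pruned feature set:", length(x$kept), "kept,",
      nrow(x$removed), "removed at |r| >=", x$cutoff, "\n")
  invisible(x)
}

#' Train the episignature SVM
#'
#' Standardizes the pruned signature CpGs by their training mean/SD and
#' fits a support vector machine in probability mode (Platt sigmoid
#' calibration fitted by libsvm's internal cross-validation under a fixed
#' seed). The returned model carries everything scoring needs -- feature
#' list, standardization, collapsed linear weights (for the linear
#' kernel), calibration coefficients and imputation means -- so a
#' serialized model scores new samples deterministically without the
#' original training data.
#'
#' @param beta Beta tibble with the training samples.
#' @param sheet Sample sheet; training samples are the `discovery_*`
#'   roles.
#' @param features An `episig_pruned` object or character vector of probe
#'   ids.
#' @param cost SVM cost parameter (default 1).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param seed Seed for the calibration cross-validation.
#' @return An object of class `episig_classifier`.
#' @export
train_classifier <- function(beta, sheet, features, cost = 1,
                             kernel = c("linear", "radial"), seed = 1L) {
  kernel <- match.arg(kernel)
  sheet <- validate_sample_sheet(sheet)
  feats <- if (inherits(features, "episig_pruned")) features$kept else features
  train_sheet <- dplyr::filter(sheet, .data$role %in%
                                 c("discovery_case", "discovery_control"))
  if (length(unique(train_sheet$group)) < 2) {
    abort("training set must contain both classes")
  }
  m <- beta_to_matrix(beta)
  miss_s <- setdiff(train_sheet$sample_id, colnames(m))
  if (length(miss_s) > 0) {
    abort(paste0("training samples missing from beta matrix: ",
                 paste(miss_s, collapse = ", ")))
  }
  miss_f <- setdiff(feats, rownames(m))
  if (length(miss_f) > 0) {
    abort(paste0("features missing from beta matrix: ",
                 paste(head(miss_f, 10), collapse = ", ")))
  }
  X <- t(m[feats, train_sheet$sample_id, drop = FALSE])
  ctrl_means <- colMeans(X[train_sheet$group == "control", , drop = FALSE],
                         na.rm = TRUE)
  if (anyNA(X)) {
    warn("missing training values imputed with training-control means")
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- ctrl_means[idx[, 2]]
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  y <- factor(train_sheet$group, levels = c("control", "case"))

  set.seed(seed)
  fit <- e1071::svm(Xs, y, kernel = kernel, cost = cost,
                    probability = TRUE, scale = FALSE)
  # libsvm orients decision values (and the Platt sigmoid) toward its
  # internal first class, which is the class seen first in the training
  # data -- not the first factor level
  first_class <- fit$levels[fit$labels[1]]
  model <- list(
    features = feats,
    center = setNames(as.numeric(center), feats),
    scale = setNames(as.numeric(scale_), feats),
    impute_means = setNames(as.numeric(ctrl_means), feats),
    kernel = kernel,
    cost = cost,
    gamma = fit$gamma,
    support_vectors = unname(as.matrix(fit$SV)),
    dual_coefs = as.numeric(fit$coefs),
    rho = fit$rho,
    prob_a = fit$probA,
    prob_b = fit$probB,
    # P(first_class) = 1 / (1 + exp(prob_a * f + prob_b))
    first_class = first_class,
    classes = levels(y),
    seed = as.integer(seed)
  )
  if (kernel == "linear") {
    model$weights <- as.numeric(crossprod(fit$coefs, as.matrix(fit$SV)))
  }
  model <- structure(model, class = "episig_classifier")
  # guard: the serialized scorer must reproduce e1071's own calibrated
  # case probabilities on the training data
  ref <- attr(predict(fit, Xs, probability = TRUE), "probabilities")[, "case"]
  own <- score_training(model, Xs)
  if (max(abs(own - ref)) > 1e-6) {
    abort("internal error: serialized scorer disagrees with fitted SVM")
  }
  model
}

#' @export
print.episig_classifier <- function(x, ...) {
  cat("Episignature SVM:", length(x$features), "CpGs,", x$kernel,
      "kernel, cost", x$cost, "\n")
  cat("Platt calibration: A =", format(x$prob_a), ", B =",
      format(x$prob_b), "\n")
  invisible(x)
}

score_training <- function(model, Xs) {
  f <- classifier_decision(model, Xs)
  p_first <- 1 / (1 + exp(model$prob_a * f + model$prob_b))
  if (model$first_class == "case") p_first else 1 - p_first
}

classifier_decision <- function(model, Xs) {
  if (model$kernel == "linear") {
    drop(Xs %*% model$weights) - model$rho
  } else {
    K <- exp(-model$gamma *
               outer(rowSums(Xs^2), rowSums(model$support_vectors^2), "+") +
               2 * model$gamma * tcrossprod(Xs, model$support_vectors))
    drop(K %*% model$dual_coefs) - model$rho
  }
}

#' Score samples with a trained episignature model
#'
#' Computes the calibrated case probability for each sample and calls it
#' `high` (case-like) when the score exceeds 0.5, `low` otherwise. A score
#' of exactly 0.5 is called `low` with a warning. Samples missing more
#' than `max_missing` of the model features are flagged unscoreable
#' (`NA` score); smaller gaps are imputed with the training-control means
#' stored in the model.
#'
#' @param model An `episig_classifier` (possibly read back from JSON).
#' @param beta Beta tibble with the samples to score.
#' @param max_missing Maximum tolerated fraction of missing model features
#'   per sample (default 0.20).
#' @return Tibble: `sample_id`, `score`, `call`, `n_missing`, `scoreable`.
#' @export
score_samples <- function(model, beta, max_missing = 0.20) {
  stopifnot(inherits(model, "episig_classifier"))
  validate_beta(beta)
  m <- beta_to_matrix(beta)
  absent <- setdiff(model$features, rownames(m))
  X <- t(rbind(m[intersect(model$features, rownames(m)), , drop = FALSE],
               matrix(NA_real_, length(absent), ncol(m),
                      dimnames = list(absent, colnames(m))))[model$features, ,
                                                             drop = FALSE])
  n_missing <- rowSums(is.na(X))
  scoreable <- n_missing <= max_missing * length(model$features)
  if (any(is.na(X))) {
    if (any(n_missing[scoreable] > 0)) {
      warn("missing feature values imputed with training-control means")
    }
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- model$impute_means[idx[, 2]]
  }
  Xs <- scale(X, center = model$center[model$features],
              scale = model$scale[model$features])
  f <- classifier_decision(model, Xs)
  p_first <- 1 / (1 + exp(model$prob_a * f + model$prob_b))
  score <- if (model$first_class == "case") p_first else 1 - p_first
  score[!scoreable] <- NA_real_
  if (any(!is.na(score) & score == 0.5)) {
    warn("score exactly 0.5 called 'low' (boundary is undefined)")
  }
  tibble(sample_id = rownames(X),
         score = as.numeric(score),
         call = dplyr::case_when(is.na(score) ~ NA_character_,
                                 score > 0.5 ~ "high",
                                 TRUE ~ "low"),
         n_missing = as.integer(n_missing),
         scoreable = scoreable)
}

#' Sensitivity / specificity by cohort
#'
#' For cohorts expected to be case-like, sensitivity is the fraction of
#' scoreable samples called `high`; for control-like cohorts, specificity
#' is the fraction called `low`. Empty cohorts are skipped with a warning.
#'
#' @param scores Tibble from [score_samples()] with an added `cohort`
#'   column.
#' @param expected Named character vector mapping cohort label to expected
#'   class (`"case"` or `"control"`).
#' @return Tibble per cohort: `cohort`, `expected`, `n`, `sensitivity`,
#'   `specificity`, `min_score`, `max_score`.
#' @export
evaluate_cohorts <- function(scores, expected) {
  if (!"cohort" %in% names(scores)) abort("scores need a 'cohort' column")
  rows <- purrr::imap(expected, function(class, label) {
    sub <- dplyr::filter(scores, .data$cohort == label, .data$scoreable)
    if (nrow(sub) == 0) {
      warn(paste0("cohort '", label, "' is empty; skipped"))
      return(NULL)
    }
    tibble(cohort = label,
           expected = class,
           n = nrow(sub),
           sensitivity = if (class == "case") mean(sub$call == "high") else NA_real_,
           specificity = if (class == "control") mean(sub$call == "low") else NA_real_,
           min_score = min(sub$score),
           max_score = max(sub$score))
  })
  dplyr::bind_rows(rows)
}

#' Serialize / restore a classifier as JSON
#'
#' The JSON model is self-contained: reading it back yields an
#' `episig_classifier` that scores identically to the in-memory original.
#'
#' @param model An `episig_classifier`.
#' @param path Output / input path.
#' @return `write_classifier()`: `path`, invisibly; `read_classifier()`:
#'   an `episig_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "episig_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$features <- as.character(x$features)
  for (f in c("center", "scale", "impute_means")) {
    x[[f]] <- setNames(as.numeric(x[[f]]), x$features)
  }
  x$support_vectors <- as.matrix(x$support_vectors)
  x$dual_coefs <- as.numeric(x$dual_coefs)
  if (!is.null(x$weights)) x$weights <- as.numeric(x$weights)
  structure(x, class = "episig_classifier")
}
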