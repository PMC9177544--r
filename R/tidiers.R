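#' Tidy a differential-methylation fit
#'
#' @param x An `episig_diffmeth`.
#' @param ... Unused.
#' @return The per-CpG tibble (`probe_id`, `coef`, `delta_beta`, `sigma`,
#'   `df_residual`, `moderated_t`, `p_value`, `q_value`, `direction`,
#'   `ok`).
#' @method tidy episig_diffmeth
#' @export
tidy.episig_diffmeth <- function(x, ...) {
  x$table
}

#' Glance at a differential-methylation fit
#'
#' @param x An `episig_diffmeth`.
#' @param q_max,min_abs_delta Signature thresholds used for the
#'   `n_signature` count.
#' @param ... Unused.
#' @return One-row tibble: `n_probes`, `n_samples`, `d0`, `s0_sq`,
#'   `n_signature`.
#' @method glance episig_diffmeth
#' @export
glance.episig_diffmeth <- function(x, q_max = 0.05, min_abs_delta = 0.10,
                                   ...) {
  sig <- suppressWarnings(select_signature(x, q_max, min_abs_delta))
  tibble(n_probes = nrow(x$table),
         n_samples = x$n_samples,
         d0 = x$d0,
         s0_sq = x$s0_sq,
         n_signature = nrow(sig))
}

#' Tidy a trained episignature classifier
#'
#' @param x An `episig_classifier`.
#' @param ... Unused.
#' @return Tibble per feature: `probe_id`, `center`, `scale`, and (linear
#'   kernel) `weight`.
#' @method tidy episig_classifier
#' @export
tidy.episig_classifier <- function(x, ...) {
  out <- tibble(probe_id = x$features,
                center = unname(x$center[x$features]),
                scale = unname(x$scale[x$features]))
  if (!is.null(x$weights)) out$weight <- x$weights
  out
}

#' Glance at a trained episignature classifier
#'
#' @param x An `episig_classifier`.
#' @param ... Unused.
#' @return One-row tibble: `n_features`, `kernel`, `cost`,
#'   `n_support_vectors`, `prob_a`, `prob_b`, `seed`.
#' @method glance episig_classifier
#' @export
glance.episig_classifier <- function(x, ...) {
  tibble(n_features = length(x$features),
         kernel = x$kernel,
         cost = x$cost,
         n_support_vectors = nrow(x$support_vectors),
         prob_a = x$prob_a,
         prob_b = x$prob_b,
         seed = x$seed)
}
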