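#' Flag probes failing detection
#'
#' A probe fails detection when its detection p-value exceeds
#' `p_threshold` in at least `sample_fraction` of samples. The default
#' (`sample_fraction = NULL`) flags a probe failing in any single sample,
#' the usual conservative rule for small cohorts.
#'
#' @param detp Detection p-value tibble laid out like a beta matrix
#'   (`probe_id` plus one numeric column per sample).
#' @param p_threshold Detection p-value cutoff, in (0, 1].
#' @param sample_fraction Minimum fraction of samples failing, in (0, 1];
#'   `NULL` means ">= 1 sample".
#' @return Character vector of flagged probe ids.
#' @export
flag_detection_failures <- function(detp, p_threshold = 0.01,
                                    sample_fraction = NULL) {
  if (p_threshold <= 0 || p_threshold > 1) abort("p_threshold must be in (0, 1]")
  m <- beta_like_matrix(detp)
  fail <- rowMeans(m > p_threshold, na.rm = TRUE)
  if (is.null(sample_fraction)) {
    flagged <- rowSums(m > p_threshold, na.rm = TRUE) >= 1
  } else {
    if (sample_fraction <= 0 || sample_fraction > 1) {
      abort("sample_fraction must be in (0, 1]")
    }
    flagged <- fail >= sample_fraction
  }
  rownames(m)[flagged]
}

beta_like_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || names(tbl)[1] != "probe_id") {
    abort("expected a probe_id-first tibble")
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$probe_id
  m
}

qc_rules <- c("detection", "snp", "cross_reactive", "extreme_beta",
              "non_cpg", "sex_chromosome")

#' Apply probe-exclusion rules
#'
#' Runs the six standard array-QC rules in a fixed order -- detection
#' failures, SNP-proximal probes (MAF above `snp_maf_max`), cross-reactive
#' probes, probes with a raw beta of exactly 0 or 1 in more than
#' `extreme_beta_fraction` of samples, non-CpG probes, and X/Y-chromosome
#' probes -- and returns the filtered matrix together with a per-rule
#' report. Rule categories overlap, so the report carries both
#' `matched` (probes satisfying the rule regardless of earlier rules) and
#' `removed` (incremental removals in application order);
#' `n_input = n_remaining + sum(removed)` always holds.
#'
#' @param beta Beta tibble.
#' @param manifest Probe manifest covering every beta probe.
#' @param detp Optional detection p-value tibble; without it the detection
#'   rule matches nothing.
#' @param p_threshold,sample_fraction Passed to [flag_detection_failures()].
#' @param snp_maf_max Probes with `snp_maf > snp_maf_max` are removed
#'   (default 0.01, i.e. MAF above 1%).
#' @param extreme_beta_fraction A probe is removed when the share of
#'   samples with beta exactly 0 or 1 (within `extreme_beta_tol`) exceeds
#'   this (default 0.0025, i.e. 0.25% -- with 34 samples a single extreme
#'   value suffices).
#' @param extreme_beta_tol Numeric tolerance for "exactly 0 or 1"
#'   (default 0: literal endpoints).
#' @return List with `beta` (filtered tibble) and `report` (tibble with
#'   columns `rule`, `matched`, `removed`, plus attributes `n_input` and
#'   `n_remaining`).
#' @export
filter_probes <- function(beta, manifest, detp = NULL,
                          p_threshold = 0.01, sample_fraction = NULL,
                          snp_maf_max = 0.01,
                          extreme_beta_fraction = 0.0025,
                          extreme_beta_tol = 0) {
  validate_beta(beta)
  manifest <- validate_manifest(manifest)
  absent <- setdiff(beta$probe_id, manifest$probe_id)
  if (length(absent) > 0) {
    abort(paste0("probes absent from manifest: ",
                 paste(head(absent, 10), collapse = ", "),
                 if (length(absent) > 10) ", ..."))
  }
  m <- beta_to_matrix(beta)
  ann <- manifest[match(rownames(m), manifest$probe_id), ]

  matched <- list()
  matched$detection <- if (is.null(detp)) character(0) else {
    intersect(flag_detection_failures(detp, p_threshold, sample_fraction),
              rownames(m))
  }
  matched$snp <- rownames(m)[!is.na(ann$snp_maf) & ann$snp_maf > snp_maf_max]
  matched$cross_reactive <- rownames(m)[!is.na(ann$cross_reactive) & ann$cross_reactive]
  extreme <- rowMeans(abs(m) <= extreme_beta_tol | abs(m - 1) <= extreme_beta_tol,
                      na.rm = TRUE)
  extreme[!is.finite(extreme)] <- 0
  matched$extreme_beta <- rownames(m)[extreme > extreme_beta_fraction]
  matched$non_cpg <- rownames(m)[ann$probe_class != "cg"]
  matched$sex_chromosome <- rownames(m)[ann$chrom %in% c("X", "Y", "chrX", "chrY")]

  n_input <- nrow(m)
  remaining <- rownames(m)
  removed <- integer(length(qc_rules))
  names(removed) <- qc_rules
  for (rule in qc_rules) {
    drop <- intersect(remaining, matched[[rule]])
    removed[rule] <- length(drop)
    remaining <- setdiff(remaining, drop)
  }

  report <- tibble(
    rule = qc_rules,
    matched = vapply(matched[qc_rules], length, 1L),
    removed = unname(removed)
  )
  attr(report, "n_input") <- n_input
  attr(report, "n_remaining") <- length(remaining)

  list(beta = beta[match(remaining, beta$probe_id), ], report = report)
}
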