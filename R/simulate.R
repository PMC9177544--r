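#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: an 8-case vs
#' 26-control discovery cohort, 6 validation cases and 100 validation
#' controls, planted signature effects of 0.10-0.25 on the beta scale with
#' mixed sign, a +14.4-year epigenetic age acceleration in cases, a
#' 6-cell-type blood reference with Dirichlet-distributed neutrophil-
#' dominant composition, and island/shore membership of 55% among
#' signature CpGs versus 37% in the background.
#'
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from
#'   it.
#' @param n_probes Total probes on the synthetic array.
#' @param n_signature Number of planted differential CpGs.
#' @param delta_range Magnitude range of planted beta differences; signs
#'   are mixed roughly 50/50.
#' @param n_case,n_control Discovery cohort sizes.
#' @param n_validation_case,n_validation_control Validation cohort sizes.
#' @param noise_sd Per-value Gaussian noise SD on the logit scale.
#' @param cell_types Blood cell-type labels.
#' @param dirichlet_alpha Dirichlet concentration per cell type (defaults
#'   centered on a neutrophil-dominant whole-blood composition).
#' @param n_deconv_cpgs Reference-panel CpGs.
#' @param n_clock_cpgs Clock CpGs.
#' @param clock_noise_sd Beta-scale noise SD at clock CpGs (0 gives exact
#'   age recovery).
#' @param acceleration_years Mean planted DNAm age acceleration for
#'   case-like samples.
#' @param acceleration_sd Between-individual SD of the planted case
#'   acceleration (years); affected individuals vary widely around the
#'   cohort mean.
#' @param control_accel_sd SD of control clock deviations (years),
#'   emulating the typical error of blood epigenetic clocks.
#' @param island_shore_signature,island_shore_background Probability that
#'   a signature / background probe is annotated Island or Shore.
#' @param n_other_signature Size of a disjoint second episignature (for
#'   other-syndrome specificity cohorts); 0 disables it.
#' @param case_age_range,control_age_range Uniform chronological age
#'   ranges (years).
#' @return A list of class `episig_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 20000,
                       n_signature = 40,
                       delta_range = c(0.10, 0.25),
                       n_case = 8, n_control = 26,
                       n_validation_case = 6, n_validation_control = 100,
                       noise_sd = 0.05,
                       cell_types = c("CD4T", "CD8T", "NK", "Bcell",
                                      "Mono", "Neu"),
                       dirichlet_alpha = 30 * c(0.17, 0.10, 0.05, 0.08,
                                                0.08, 0.52),
                       n_deconv_cpgs = 600,
                       n_clock_cpgs = 100,
                       clock_noise_sd = 0.005,
                       acceleration_years = 14.4,
                       acceleration_sd = 4,
                       control_accel_sd = 3,
                       island_shore_signature = 0.55,
                       island_shore_background = 0.37,
                       n_other_signature = 40,
                       case_age_range = c(4, 31),
                       control_age_range = c(4, 35)) {
  cfg <- as.list(environment())
  if (any(c(cfg$n_probes, cfg$n_signature, cfg$n_case, cfg$n_control) <= 0)) {
    abort("counts must be positive")
  }
  if (cfg$delta_range[1] <= 0 || cfg$delta_range[2] >= 1 ||
      cfg$delta_range[1] > cfg$delta_range[2]) {
    abort("delta_range must be increasing and within (0, 1)")
  }
  if (length(cfg$dirichlet_alpha) != length(cfg$cell_types)) {
    abort("dirichlet_alpha must match cell_types")
  }
  needed <- cfg$n_signature + cfg$n_other_signature + cfg$n_deconv_cpgs +
    cfg$n_clock_cpgs + 60
  if (cfg$n_probes < needed + 100) {
    abort(paste0("n_probes too small for the configured blocks (need > ",
                 needed + 100, ")"))
  }
  structure(cfg, class = "episig_sim_config")
}

rdirichlet_mat <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# logit offset that moves a baseline beta by exactly delta at zero noise
logit_offset <- function(baseline, delta) {
  qlogis(clip01(baseline + delta)) - qlogis(baseline)
}

#' Simulate a full synthetic cohort
#'
#' Generates every input the pipeline consumes: a beta matrix with planted
#' differential CpGs, deconvolution CpGs driven by per-sample cell
#' mixtures, clock CpGs encoding each sample's (possibly accelerated)
#' age, QC-decoy probes (non-CpG, X/Y, cross-reactive, SNP-proximal,
#' extreme-beta), a matching sample sheet, probe manifest with gene spans,
#' cell reference panel, clock model, and truth tables for every planted
#' quantity. Identical seeds give identical output.
#'
#' Per-probe baselines are drawn from a bimodal distribution (methylation
#' is mostly near 0 or 1); per-sample values are
#' `plogis(qlogis(baseline) + group offset + noise)`, where the group
#' offset at signature CpGs is calibrated in closed form so the realized
#' mean case-control difference matches the configured delta at the
#' baseline.
#'
#' @param config An `episig_sim_config` from [sim_config()].
#' @return A list of class `episig_sim`: `beta`, `sheet`, `manifest`,
#'   `cell_reference`, `clock`, `truth` (list of tibbles: `signature`,
#'   `other_signature`, `proportions`, `ages`), plus the generator
#'   internals used by [simulate_test_samples()].
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "episig_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## ---- probe layout --------------------------------------------------
  n_decoy <- 60
  ids <- sprintf("cg%08d", seq_len(cfg$n_probes))
  block <- rep("background", cfg$n_probes)
  cursor <- 0
  take <- function(n) {
    out <- (cursor + 1):(cursor + n)
    cursor <<- cursor + n
    out
  }
  i_sig <- take(cfg$n_signature); block[i_sig] <- "signature"
  i_other <- if (cfg$n_other_signature > 0) take(cfg$n_other_signature) else integer(0)
  block[i_other] <- "other_signature"
  i_deconv <- take(cfg$n_deconv_cpgs); block[i_deconv] <- "deconv"
  i_clock <- take(cfg$n_clock_cpgs); block[i_clock] <- "clock"
  i_decoy <- take(n_decoy); block[i_decoy] <- "decoy"
  ids[i_decoy[51:60]] <- sprintf("ch%08d", 1:10)  # non-CpG decoys

  ## ---- baselines -----------------------------------------------------
  hi <- runif(cfg$n_probes) < 0.5
  baseline <- ifelse(hi, rbeta(cfg$n_probes, 45, 5), rbeta(cfg$n_probes, 5, 45))
  baseline[c(i_sig, i_other)] <- runif(length(c(i_sig, i_other)), 0.30, 0.60)
  baseline <- clip01(baseline)

  ## planted effects (signed deltas; baselines chosen so beta+delta stays
  ## inside (0, 1))
  sig_delta <- sample(c(-1, 1), cfg$n_signature, replace = TRUE) *
    runif(cfg$n_signature, cfg$delta_range[1], cfg$delta_range[2])
  other_delta <- if (length(i_other)) {
    sample(c(-1, 1), length(i_other), replace = TRUE) *
      runif(length(i_other), cfg$delta_range[1], cfg$delta_range[2])
  } else numeric(0)
  sig_offset <- logit_offset(baseline[i_sig], sig_delta)
  other_offset <- logit_offset(baseline[i_other], other_delta)

  ## ---- cell reference ------------------------------------------------
  k <- length(cfg$cell_types)
  disc <- rep_len(seq_len(k), cfg$n_deconv_cpgs)
  R <- matrix(runif(cfg$n_deconv_cpgs * k, 0.05, 0.20),
              cfg$n_deconv_cpgs, k)
  R[cbind(seq_len(cfg$n_deconv_cpgs), disc)] <- runif(cfg$n_deconv_cpgs, 0.70, 0.90)
  colnames(R) <- cfg$cell_types
  rownames(R) <- ids[i_deconv]

  ## ---- clock ---------------------------------------------------------
  clock_intercept <- -3.1
  w <- runif(cfg$n_clock_cpgs, 0.8, 1.2)
  w <- w * 6 / sum(w)
  clock <- clock_model(clock_intercept,
                       setNames(w, ids[i_clock]), adult_age = 20)

  ## ---- samples -------------------------------------------------------
  roles <- c(rep("discovery_case", cfg$n_case),
             rep("discovery_control", cfg$n_control),
             rep("validation_case", cfg$n_validation_case),
             rep("validation_control", cfg$n_validation_control))
  n_s <- length(roles)
  is_case <- grepl("_case$", roles)
  sheet <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_s)),
    group = ifelse(is_case, "case", "control"),
    role = roles,
    sex = rep_len(c("F", "M"), n_s),
    age_years = ifelse(is_case,
                       runif(n_s, cfg$case_age_range[1], cfg$case_age_range[2]),
                       runif(n_s, cfg$control_age_range[1], cfg$control_age_range[2]))
  )
  props <- rdirichlet_mat(n_s, cfg$dirichlet_alpha)
  colnames(props) <- cfg$cell_types
  accel <- ifelse(is_case,
                  rnorm(n_s, cfg$acceleration_years, cfg$acceleration_sd),
                  rnorm(n_s, 0, cfg$control_accel_sd))
  accel <- pmax(accel, -sheet$age_years)  # DNAm age cannot go below 0

  internals <- list(config = cfg, ids = ids, block = block,
                    baseline = baseline,
                    i_sig = i_sig, i_other = i_other,
                    i_deconv = i_deconv, i_clock = i_clock,
                    i_decoy = i_decoy,
                    sig_offset = sig_offset, other_offset = other_offset,
                    reference = R, clock = clock, clock_w = w)

  m <- draw_samples(internals, sheet$sample_id,
                    signature_on = is_case, other_on = rep(FALSE, n_s),
                    accel = accel, props = props, ages = sheet$age_years)

  ## extreme-beta decoys: force endpoint values in a few samples
  m[i_decoy[41:50], seq_len(min(3, n_s))] <- rep(c(0, 1, 0), length.out = 10 * min(3, n_s))

  ## ---- manifest ------------------------------------------------------
  rel_bg <- c(Island = 0.22, Shore = 0.15, Shelf = 0.13, OpenSea = 0.50)
  p_is <- cfg$island_shore_signature
  rel_sig <- c(Island = p_is * 0.6, Shore = p_is * 0.4,
               Shelf = (1 - p_is) * 0.25, OpenSea = (1 - p_is) * 0.75)
  island_relation <- sample(names(rel_bg), cfg$n_probes, replace = TRUE,
                            prob = rel_bg)
  island_relation[i_sig] <- sample(names(rel_sig), cfg$n_signature,
                                   replace = TRUE, prob = rel_sig)
  chrom <- paste0("chr", rep_len(1:22, cfg$n_probes))
  chrom[i_decoy[11:20]] <- "chrX"
  chrom[i_decoy[21:30]] <- "chrY"
  pos <- 10000 + 137 * seq_len(cfg$n_probes)
  snp_maf <- rep(NA_real_, cfg$n_probes)
  snp_maf[i_decoy[31:40]] <- runif(10, 0.05, 0.4)
  cross_reactive <- rep(FALSE, cfg$n_probes)
  cross_reactive[i_decoy[1:10]] <- TRUE
  probe_class <- ifelse(startsWith(ids, "ch"), "ch", "cg")

  ## gene spans: ~60% of signature probes and 25% of background probes get
  ## a nearby gene; some genes deliberately span two signature CpGs
  genes <- rep(NA_character_, cfg$n_probes)
  with_gene <- c(i_sig[runif(length(i_sig)) < 0.6],
                 sample(which(block == "background"),
                        round(0.25 * sum(block == "background"))))
  gene_id <- sprintf("GENE%05d", seq_along(with_gene))
  g_start <- pos[with_gene] - sample(0:8000, length(with_gene), replace = TRUE)
  g_end <- pos[with_gene] + sample(100:5000, length(with_gene), replace = TRUE)
  genes[with_gene] <- sprintf("%s:%d-%d:+", gene_id, g_start, g_end)
  manifest <- tibble(probe_id = ids, chrom = chrom, pos = pos,
                     probe_class = probe_class,
                     island_relation = island_relation,
                     snp_maf = snp_maf, cross_reactive = cross_reactive,
                     genes = genes)

  structure(list(
    beta = matrix_to_beta(m),
    sheet = sheet,
    manifest = manifest,
    cell_reference = matrix_to_beta(R),
    clock = clock,
    truth = list(
      signature = tibble(probe_id = ids[i_sig], delta = sig_delta,
                         baseline = baseline[i_sig]),
      other_signature = tibble(probe_id = ids[i_other], delta = other_delta,
                               baseline = baseline[i_other]),
      proportions = dplyr::bind_cols(tibble(sample_id = sheet$sample_id),
                                     as_tibble(props)),
      ages = tibble(sample_id = sheet$sample_id,
                    age_years = sheet$age_years,
                    acceleration = accel)
    ),
    internals = internals
  ), class = "episig_sim")
}

## core sample generator shared by simulate_cohort / simulate_test_samples
draw_samples <- function(int, sample_ids, signature_on, other_on, accel,
                         props, ages) {
  cfg <- int$config
  n_s <- length(sample_ids)
  n_p <- cfg$n_probes
  base_logit <- qlogis(pmin(1 - 1e-6, pmax(1e-6, int$baseline)))
  m <- matrix(base_logit, n_p, n_s)
  if (any(signature_on)) {
    m[int$i_sig, signature_on] <- m[int$i_sig, signature_on] + int$sig_offset
  }
  if (any(other_on) && length(int$i_other)) {
    m[int$i_other, other_on] <- m[int$i_other, other_on] + int$other_offset
  }
  m <- plogis(m + matrix(rnorm(n_p * n_s, sd = cfg$noise_sd), n_p, n_s))

  ## deconvolution CpGs: linear mixture of the reference
  m[int$i_deconv, ] <- clip01(int$reference %*% t(props) +
                                matrix(rnorm(length(int$i_deconv) * n_s,
                                             sd = 0.01),
                                       length(int$i_deconv), n_s))
  ## clock CpGs: encode transform_age(age + acceleration); DNAm age
  ## cannot go below 0
  lp <- transform_age(pmax(ages + accel, 0), int$clock$adult_age) -
    int$clock$intercept
  b <- outer(rep(1 / sum(int$clock_w), cfg$n_clock_cpgs), lp)
  if (cfg$clock_noise_sd > 0) {
    b <- b + matrix(rnorm(length(b), sd = cfg$clock_noise_sd), nrow(b))
  }
  m[int$i_clock, ] <- clip01(b)

  rownames(m) <- int$ids
  colnames(m) <- sample_ids
  m
}

#' Simulate additional test samples
#'
#' Draws new samples from a previously simulated cohort's generator:
#' `case_like` samples carry the planted signature (and the planted age
#' acceleration), `control_like` samples carry neither, and
#' `other_signature` samples carry the disjoint second signature only --
#' the synthetic analogue of scoring variant carriers, unaffected
#' controls, and other-syndrome cohorts.
#'
#' @param sim An `episig_sim` from [simulate_cohort()].
#' @param kind One of `"case_like"`, `"control_like"`,
#'   `"other_signature"`.
#' @param n Number of samples.
#' @param seed Seed for the new draws.
#' @param prefix Sample-id prefix.
#' @return List with `beta` and `sheet` (role `"test"`).
#' @export
simulate_test_samples <- function(sim, kind = c("case_like", "control_like",
                                                "other_signature"),
                                  n, seed = 1L, prefix = NULL) {
  stopifnot(inherits(sim, "episig_sim"))
  kind <- match.arg(kind)
  int <- sim$internals
  cfg <- int$config
  if (kind == "other_signature" && length(int$i_other) == 0) {
    abort("no second signature configured; set n_other_signature > 0")
  }
  set.seed(seed)
  prefix <- prefix %||% toupper(substr(kind, 1, 1))
  sample_ids <- sprintf("%s%03d", prefix, seq_len(n))
  ages <- runif(n, cfg$case_age_range[1], cfg$case_age_range[2])
  is_case <- kind == "case_like"
  props <- rdirichlet_mat(n, cfg$dirichlet_alpha)
  accel <- if (is_case) {
    rnorm(n, cfg$acceleration_years, cfg$acceleration_sd)
  } else {
    rnorm(n, 0, cfg$control_accel_sd)
  }
  accel <- pmax(accel, -ages)
  m <- draw_samples(int, sample_ids,
                    signature_on = rep(is_case, n),
                    other_on = rep(kind == "other_signature", n),
                    accel = accel,
                    props = props, ages = ages)
  list(beta = matrix_to_beta(m),
       sheet = tibble(sample_id = sample_ids,
                      group = if (is_case) "case" else "control",
                      role = "test",
                      sex = rep_len(c("F", "M"), n),
                      age_years = ages))
}

#' Write degenerate edge-case fixtures
#'
#' Emits tiny plain-text fixtures exercising pipeline edge cases: a probe
#' with all-zero betas, a matrix with missing cells, a single-sex cohort
#' sheet (rank-deficient design), duplicated feature rows (pruning
#' trigger), a gene span ending exactly 10 kb from its probe (mapping
#' boundary), and an n = 1 cohort sheet.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
make_degenerate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- list()

  beta <- tibble(probe_id = c("cg_zero", "cg_dup_a", "cg_dup_b", "cg_na"),
                 A1 = c(0, 0.50, 0.50, 0.8),
                 A2 = c(0, 0.62, 0.62, NA),
                 A3 = c(0, 0.41, 0.41, 0.7))
  paths$beta <- write_beta_matrix(beta, p("degenerate_beta.tsv"))

  single_sex <- tibble(sample_id = c("A1", "A2", "A3"),
                       group = c("case", "control", "control"),
                       role = c("discovery_case", "discovery_control",
                                "discovery_control"),
                       sex = "M", age_years = c(5, 7, 9))
  readr::write_csv(single_sex, p("single_sex_sheet.csv"))
  paths$single_sex <- p("single_sex_sheet.csv")

  n1 <- tibble(sample_id = "A1", group = "case", role = "discovery_case",
               sex = "F", age_years = 7)
  readr::write_csv(n1, p("n1_sheet.csv"))
  paths$n1 <- p("n1_sheet.csv")

  manifest <- tibble(
    probe_id = c("cg_zero", "cg_dup_a", "cg_dup_b", "cg_na"),
    chrom = "chr1",
    pos = c(50000L, 60000L, 70000L, 80000L),
    probe_class = "cg",
    island_relation = c("Island", "Shore", "OpenSea", "Shelf"),
    snp_maf = NA_real_,
    cross_reactive = FALSE,
    # span end exactly 10 kb left of cg_zero's position
    genes = c("BOUND:30000-40000:+", NA, NA, NA)
  )
  readr::write_tsv(manifest, p("degenerate_manifest.tsv"))
  paths$manifest <- p("degenerate_manifest.tsv")

  invisible(paths)
}
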