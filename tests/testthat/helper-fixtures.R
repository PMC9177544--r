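# shared in-code fixtures

tiny_beta <- function() {
  tibble::tibble(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    A = c(0.10, 0.80, 0.50, 0.30, 0.90),
    B = c(0.12, 0.78, 0.55, 0.31, 0.88),
    C = c(0.11, 0.82, 0.52, 0.29, 0.91),
    D = c(0.30, 0.60, 0.50, 0.33, 0.70),
    E = c(0.32, 0.58, 0.48, 0.35, 0.72),
    F = c(0.31, 0.61, 0.51, 0.34, 0.69)
  )
}

tiny_sheet <- function() {
  tibble::tibble(
    sample_id = c("A", "B", "C", "D", "E", "F"),
    group = c("case", "case", "case", "control", "control", "control"),
    role = c(rep("discovery_case", 3), rep("discovery_control", 3)),
    sex = c("F", "M", "F", "M", "F", "M"),
    age_years = c(8, 15, 10, 9, 14, 11)
  )
}

tiny_manifest <- function() {
  tibble::tibble(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    chrom = c("chr1", "chr1", "chr2", "chrX", "chr3"),
    pos = c(100L, 5000L, 200L, 300L, 400L),
    probe_class = c("cg", "cg", "cg", "cg", "ch"),
    island_relation = c("Island", "Shore", "OpenSea", "Shelf", "Island"),
    snp_maf = c(NA, 0.2, NA, NA, NA),
    cross_reactive = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    genes = c("GENEA:90-120:+", NA, NA, NA, NA)
  )
}

# small, fast synthetic cohort for unit tests
small_sim <- function(seed = 1, ...) {
  simulate_cohort(sim_config(seed = seed, n_probes = 3000,
                             n_validation_control = 20, ...))
}

# reference discovery cohort: printed demographic table of the 8 discovery
# cases (the 2-day-old infant belongs to the validation set, not here)
discovery_sheet <- function() {
  tibble::tibble(
    sample_id = paste0("EX", 1:8),
    group = "case",
    role = "discovery_case",
    sex = c("M", "F", "F", "M", "M", "M", "F", "F"),
    age_years = c(8, 15, 10, 31, 15, 4, 4, 29)
  )
}
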