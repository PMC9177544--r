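#' Read a probe manifest
#'
#' The manifest annotates probes with genomic position (1-based, the array
#' vendor convention), probe class (`cg`, `ch`, `rs`), CpG-island relation
#' (`Island`, `Shore`, `Shelf`, `OpenSea`; a Shore is within 2 kb of an
#' Island), the minor allele frequency of any nearby SNP, a cross-reactive
#' flag, and (optionally) nearby gene spans encoded as
#' `"SYM:start-end:+;SYM2:start-end:-"` in a `genes` column.
#'
#' @param path TSV file with named columns `probe_id`, `chrom`, `pos`,
#'   `probe_class`, `island_relation`, `snp_maf`, `cross_reactive`, and
#'   optionally `genes`.
#' @return A validated tibble.
#' @export
read_manifest <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(tbl)
}

#' Validate a probe manifest
#'
#' @param manifest Data frame of probe annotations.
#' @return The manifest as a tibble.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "probe_class", "island_relation",
            "snp_maf", "cross_reactive")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0) {
    abort(paste0("manifest is missing columns: ", paste(miss, collapse = ", ")))
  }
  manifest <- as_tibble(manifest)
  manifest$probe_id <- as.character(manifest$probe_id)
  if (anyDuplicated(manifest$probe_id)) abort("duplicate probe ids in manifest")
  if (any(!is.na(manifest$pos) & manifest$pos < 1)) {
    abort("manifest positions must be 1-based (pos >= 1)")
  }
  manifest$cross_reactive <- as.logical(manifest$cross_reactive)
  manifest
}

#' Expand manifest gene annotations into a tidy span table
#'
#' @param manifest Manifest tibble with a `genes` column.
#' @return Tibble with one row per (probe, gene span): `probe_id`, `gene`,
#'   `chrom`, `span_start`, `span_end`, `strand`.
#' @export
manifest_gene_spans <- function(manifest) {
  if (!"genes" %in% names(manifest)) {
    abort("manifest has no 'genes' column")
  }
  tbl <- manifest |>
    dplyr::select("probe_id", "chrom", "genes") |>
    dplyr::filter(!is.na(.data$genes), .data$genes != "") |>
    tidyr::separate_rows("genes", sep = ";")
  if (nrow(tbl) == 0) {
    return(tibble(probe_id = character(), gene = character(),
                  chrom = character(), span_start = integer(),
                  span_end = integer(), strand = character()))
  }
  parts <- strsplit(tbl$genes, ":", fixed = TRUE)
  if (any(lengths(parts) != 3)) abort("malformed gene span; expected SYM:start-end:strand")
  span <- strsplit(vapply(parts, `[[`, "", 2), "-", fixed = TRUE)
  tbl |>
    dplyr::mutate(
      gene = vapply(parts, `[[`, "", 1),
      span_start = as.integer(vapply(span, `[[`, "", 1)),
      span_end = as.integer(vapply(span, `[[`, "", 2)),
      strand = vapply(parts, `[[`, "", 3)
    ) |>
    dplyr::select("probe_id", "gene", "chrom", "span_start", "span_end", "strand")
}

#' Export signature CpGs as BED6
#'
#' Writes one BED line per signature probe. Manifest coordinates are
#' 1-based; BED is 0-based half-open, so `start = pos - 1`, `end = pos`.
#' The name field is the probe id, the score is `round(1000 * |delta_beta|)`
#' capped at 1000, and strand is ".". An empty signature yields a file with
#' only the header comment.
#'
#' @param signature Tibble with `probe_id` and `delta_beta` columns, e.g.
#'   from [select_signature()].
#' @param manifest Probe manifest covering every signature probe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_signature_bed <- function(signature, manifest, path) {
  manifest <- validate_manifest(manifest)
  hit <- match(signature$probe_id, manifest$probe_id)
  missing_coord <- is.na(hit) | is.na(manifest$chrom[hit]) | is.na(manifest$pos[hit])
  if (any(missing_coord)) {
    abort(paste0("probes without manifest coordinates: ",
                 paste(signature$probe_id[missing_coord], collapse = ", ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# signature CpGs (BED6: chrom start end probe score strand)", con)
  if (nrow(signature) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                     manifest$chrom[hit],
                     manifest$pos[hit] - 1L,
                     manifest$pos[hit],
                     signature$probe_id,
                     pmin(1000L, as.integer(round(1000 * abs(signature$delta_beta)))))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a signature BED file back into a tibble
#'
#' @param path BED file written by [export_signature_bed()].
#' @return Tibble with `chrom`, `start`, `end`, `probe_id`, `score`,
#'   `strand`, and the recovered 1-based `pos = end`.
#' @export
read_signature_bed <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#",
                         col_names = c("chrom", "start", "end", "probe_id",
                                       "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  dplyr::mutate(tbl, pos = .data$end)
}
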