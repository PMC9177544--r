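#' Island/shore enrichment of a signature
#'
#' One-sided (upper-tail) hypergeometric test of whether signature CpGs
#' overlap CpG islands or shores more often than the background probe set
#' (the post-QC array content).
#'
#' @param signature Character vector of signature probe ids, or a tibble
#'   with a `probe_id` column.
#' @param manifest Probe manifest with `island_relation`.
#' @param background Character vector of background probe ids; every
#'   signature probe must be in it.
#' @param relations Island relations counted as hits.
#' @return One-row tibble: `N`, `K`, `n`, `k`, `foreground_fraction`,
#'   `background_fraction`, `p_value`.
#' @export
island_shore_enrichment <- function(signature, manifest, background,
                                    relations = c("Island", "Shore")) {
  fg <- if (is.data.frame(signature)) signature$probe_id else signature
  out <- setdiff(fg, background)
  if (length(out) > 0) {
    abort(paste0("signature probes not in background: ",
                 paste(head(out, 10), collapse = ", ")))
  }
  manifest <- validate_manifest(manifest)
  rel <- setNames(manifest$island_relation, manifest$probe_id)
  hit_bg <- rel[background] %in% relations
  hit_fg <- rel[fg] %in% relations
  hyper_test(N = length(background), K = sum(hit_bg),
             n = length(fg), k = sum(hit_fg))
}

hyper_test <- function(N, K, n, k) {
  tibble(N = N, K = K, n = n, k = k,
         foreground_fraction = if (n > 0) k / n else NA_real_,
         background_fraction = if (N > 0) K / N else NA_real_,
         p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Map CpGs to genes by distance
#'
#' A CpG maps to every gene whose annotated span lies within
#' `max_distance` of the probe position (inclusive at the boundary;
#' distance 0 inside the span), matching the plain distal-mapping cutoff
#' used for region-based ontology enrichment.
#'
#' @param probes Character vector of probe ids, or a tibble with
#'   `probe_id`.
#' @param manifest Probe manifest (for `chrom` / `pos`).
#' @param gene_spans Tibble of gene spans: `gene`, `chrom`, `span_start`,
#'   `span_end` (e.g. from [manifest_gene_spans()], deduplicated).
#' @param max_distance Mapping cutoff in bp (default 10000).
#' @return Tibble: `probe_id`, `gene`, `distance` (bp to the nearest span
#'   edge, 0 if inside).
#' @export
map_cpgs_to_genes <- function(probes, manifest, gene_spans,
                              max_distance = 10000) {
  ids <- if (is.data.frame(probes)) probes$probe_id else probes
  manifest <- validate_manifest(manifest)
  pos_tbl <- manifest |>
    dplyr::filter(.data$probe_id %in% ids) |>
    dplyr::select("probe_id", "chrom", "pos")
  spans <- gene_spans |>
    dplyr::select("gene", "chrom", "span_start", "span_end") |>
    dplyr::distinct()
  pos_tbl |>
    dplyr::inner_join(spans, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(distance = pmax(0, .data$span_start - .data$pos,
                                  .data$pos - .data$span_end)) |>
    dplyr::filter(.data$distance <= max_distance) |>
    dplyr::select("probe_id", "gene", "distance") |>
    dplyr::arrange(.data$probe_id, .data$gene)
}

#' Summarize a CpG-to-gene mapping
#'
#' @param mapped Tibble from [map_cpgs_to_genes()].
#' @return One-row tibble: `n_cpgs_mapped`, `n_genes`,
#'   `n_genes_multi_cpg` (genes overlapped by >= 2 CpGs).
#' @export
gene_map_summary <- function(mapped) {
  per_gene <- dplyr::count(mapped, .data$gene)
  tibble(n_cpgs_mapped = dplyr::n_distinct(mapped$probe_id),
         n_genes = nrow(per_gene),
         n_genes_multi_cpg = sum(per_gene$n >= 2))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set enrichment of mapped signature genes
#'
#' Per-term upper-tail hypergeometric test over genes: the universe is
#' `background_genes`, the foreground the signature-mapped genes, and hits
#' the term members. q-values are BH-adjusted across all tested terms;
#' reported terms need at least `min_hits` foreground genes and
#' `q < q_max`.
#'
#' @param foreground_genes Character vector of signature-mapped genes.
#' @param gene_sets Named list of gene vectors (see [read_gene_sets()]).
#' @param background_genes Character vector, the gene universe.
#' @param min_hits Minimum foreground hits for a term to be reported.
#' @param q_max FDR threshold for reporting.
#' @param report_all Return all terms (with a `reported` flag) instead of
#'   only the reported ones.
#' @return Tibble per term: `term`, `N`, `K`, `n`, `k`, `p_value`,
#'   `q_value`, `gene_hits` (list column), `reported`.
#' @export
geneset_enrichment <- function(foreground_genes, gene_sets, background_genes,
                               min_hits = 3, q_max = 0.05,
                               report_all = FALSE) {
  if (length(gene_sets) == 0) abort("gene_sets is empty")
  if (length(background_genes) == 0) abort("background gene universe is empty")
  background_genes <- unique(background_genes)
  fg <- intersect(unique(foreground_genes), background_genes)
  rows <- purrr::imap(gene_sets, function(members, term) {
    members <- intersect(unique(members), background_genes)
    hits <- intersect(fg, members)
    dplyr::mutate(
      hyper_test(N = length(background_genes), K = length(members),
                 n = length(fg), k = length(hits)),
      term = term, gene_hits = list(sort(hits))
    )
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  reported = .data$k >= min_hits & .data$q_value < q_max) |>
    dplyr::select("term", "N", "K", "n", "k", "p_value", "q_value",
                  "gene_hits", "reported") |>
    dplyr::arrange(.data$q_value, .data$term)
  if (report_all) tab else dplyr::filter(tab, .data$reported)
}
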