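#' Cohort-level recurrence of identical variants
#'
#' Finds variants retained in two or more unrelated index cases (distinct
#' `family_id`); within-family duplicates collapse to a single
#' contribution. In fixture mode variant identity is gene + HGVS-c; in VCF
#' mode it is the normalized `variant_key` — whichever populated the
#' `variant_key` column of the case results.
#'
#' @param case_results Data.frame with one row per (case, variant):
#'   `case_id`, `family_id`, `gene_symbol`, `variant_key`, `retained`.
#' @return A data.frame of clusters: `kind`, `key`, `case_ids`
#'   (comma-separated), `n_cases`.
#' @export
identical_variant_clusters <- function(case_results) {
  r <- case_results[case_results$retained, , drop = FALSE]
  r <- r[!duplicated(r[c("family_id", "variant_key")]), , drop = FALSE]
  out <- do.call(rbind, lapply(split(r, r$variant_key), function(d) {
    if (length(unique(d$family_id)) < 2L) return(NULL)
    data.frame(kind = "identical_variant", key = d$variant_key[1],
               case_ids = paste(sort(unique(d$case_id)), collapse = ","),
               n_cases = length(unique(d$family_id)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(kind = character(), key = character(),
                                      case_ids = character(),
                                      n_cases = integer(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Gene-level recurrence across unrelated cases
#'
#' One cluster per gene in which two or more unrelated cases retain any
#' variant; `distinct_variants` counts the unique variant keys involved.
#'
#' @inheritParams identical_variant_clusters
#' @return A data.frame: `kind`, `key` (gene symbol), `case_ids`,
#'   `n_cases`, `distinct_variants`.
#' @export
gene_recurrence <- function(case_results) {
  r <- case_results[case_results$retained, , drop = FALSE]
  out <- do.call(rbind, lapply(split(r, r$gene_symbol), function(d) {
    fams <- unique(d$family_id)
    if (length(fams) < 2L) return(NULL)
    data.frame(kind = "gene_level", key = d$gene_symbol[1],
               case_ids = paste(sort(unique(d$case_id)), collapse = ","),
               n_cases = length(fams),
               distinct_variants = length(unique(d$variant_key)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(kind = character(), key = character(),
                                      case_ids = character(),
                                      n_cases = integer(),
                                      distinct_variants = integer(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Retained candidate counts per index case
#'
#' @inheritParams identical_variant_clusters
#' @param case_ids Optional vector of all case ids, so cases with zero
#'   retained candidates appear with a count of 0.
#' @return Named integer vector of retained-variant counts per case.
#' @export
per_case_counts <- function(case_results, case_ids = NULL) {
  r <- case_results[case_results$retained, , drop = FALSE]
  if (is.null(case_ids)) case_ids <- unique(case_results$case_id)
  counts <- vapply(case_ids, function(cid) sum(r$case_id == cid), integer(1))
  stats::setNames(counts, case_ids)
}

#' Mean CADD Phred score over retained candidate variants
#'
#' Missing (ND) scores are excluded from numerator and denominator; when no
#' retained variant has a score the mean is undefined (`NA`).
#'
#' @inheritParams identical_variant_clusters
#' @export
mean_cadd <- function(case_results) {
  r <- case_results[case_results$retained, , drop = FALSE]
  x <- r$cadd_phred[!is.na(r$cadd_phred)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Genes sharing at least one pathway with the anchor gene
#'
#' Exact set-intersection semantics over a static gene-to-pathway map;
#' genes absent from the map contribute nothing. The anchor gene must be
#' present in the map.
#'
#' @param anchor_gene Anchor gene symbol.
#' @param gene_set Character vector of genes to test.
#' @param pathway_map Data.frame `gene`/`pathway_id` from
#'   [read_pathway_map()].
#' @return Sorted character vector of genes in `gene_set` sharing a pathway
#'   with the anchor.
#' @export
pathway_overlap <- function(anchor_gene, gene_set, pathway_map) {
  anchor_paths <- pathway_map$pathway_id[pathway_map$gene == anchor_gene]
  if (length(anchor_paths) == 0L) {
    stop(sprintf("anchor gene '%s' absent from pathway map", anchor_gene))
  }
  gene_set <- setdiff(unique(gene_set), anchor_gene)
  hits <- vapply(gene_set, function(g) {
    length(intersect(pathway_map$pathway_id[pathway_map$gene == g],
                     anchor_paths)) > 0L
  }, logical(1))
  sort(gene_set[hits])
}

#' Assemble the cohort summary
#'
#' @inheritParams identical_variant_clusters
#' @param case_ids Vector of all index case ids in the cohort (so negative
#'   cases count toward `n_index`).
#' @return A list: `n_index`, `n_positive` (cases with at least one
#'   retained pair), `per_case_candidate_counts`, `mean_cadd`,
#'   `effect_class_fractions`, `recurrence` (identical-variant and
#'   gene-level clusters).
#' @export
cohort_summary <- function(case_results, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- unique(case_results$case_id)
  counts <- per_case_counts(case_results, case_ids)
  eff <- effect_class_summary(case_results)
  list(n_index = length(case_ids),
       n_positive = sum(counts >= 1L),
       per_case_candidate_counts = as.list(counts),
       mean_cadd = mean_cadd(case_results),
       effect_class_counts = as.list(eff$counts),
       effect_class_fractions = as.list(eff$fractions),
       recurrence = list(
         identical_variant = identical_variant_clusters(case_results),
         gene_level = gene_recurrence(case_results)))
}
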