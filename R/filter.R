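#' Configuration of the rare-variant filter cascade
#'
#' Holds the four filter parameters applied, in fixed order, to every
#' variant observed in an index case: read depth, predicted consequence,
#' population allele frequency and gene-panel membership. Defaults mirror
#' the tailored exome filtering used for anchor-gene DSD cohorts: depth of
#' 20 or more, gnomAD MAF at most 0.01 (karyotype-aware on the sex
#' chromosomes), all consequences except synonymous, and a panel of DSD and
#' SF-1 related genes.
#'
#' @param min_depth Minimum read depth, inclusive (default 20).
#' @param max_maf Maximum minor allele frequency, inclusive (default 0.01).
#' @param excluded_consequences Consequence classes removed by the filter
#'   (default `"synonymous"`).
#' @param panel Gene panel data.frame (`gene`, `category`) as returned by
#'   [read_gene_panel()] or [default_panel()].
#' @param karyotype_aware_maf Compare the XY-specific frequency for sex
#'   chromosome variants in 46,XY individuals when available (default TRUE).
#' @param anchor_gene Anchor gene symbol, always retained by the panel
#'   filter.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 20L, max_maf = 0.01,
                          excluded_consequences = "synonymous",
                          panel = default_panel(),
                          karyotype_aware_maf = TRUE,
                          anchor_gene = default_anchor_gene()) {
  stopifnot(min_depth >= 0, max_maf >= 0, max_maf <= 1)
  match_arg_vec(excluded_consequences, consequence_levels(),
                "excluded consequence")
  structure(list(min_depth = as.integer(min_depth), max_maf = max_maf,
                 excluded_consequences = excluded_consequences,
                 panel = panel, karyotype_aware_maf = karyotype_aware_maf,
                 anchor_gene = anchor_gene),
            class = "filter_config")
}

#' Individual filter predicates
#'
#' The four elementary predicates of the cascade, exposed separately so they
#' can be audited and property-tested. All boundaries are inclusive on the
#' retained side: depth `>= min_depth`, frequency `<= max_maf`.
#'
#' @param depth Integer read depth, `NA` when unknown.
#' @param config A [filter_config()].
#' @return Logical vector, `TRUE` where the variant passes.
#' @name filter_predicates
NULL

#' @rdname filter_predicates
#' @export
apply_depth_filter <- function(depth, config) {
  !is.na(depth) & depth >= config$min_depth
}

#' @rdname filter_predicates
#' @param consequence Consequence class strings.
#' @export
apply_consequence_filter <- function(consequence, config) {
  if (any(consequence == "other", na.rm = TRUE)) {
    warning("consequence 'other' passes the consequence filter unexamined")
  }
  !is.na(consequence) & !(consequence %in% config$excluded_consequences)
}

#' @rdname filter_predicates
#' @param gnomad_af,gnomad_af_xy Population allele frequencies (`NA` when the
#'   variant is absent from gnomAD).
#' @param chrom Contig of each variant.
#' @param karyotype Karyotype of the individual being filtered.
#' @return For `apply_maf_filter`, a data.frame with `pass` and `flag`
#'   (`"absent_from_gnomad"` where the rarity presumption applied).
#' @export
apply_maf_filter <- function(gnomad_af, gnomad_af_xy, chrom, karyotype,
                             config) {
  use_xy <- config$karyotype_aware_maf & karyotype == "46,XY" &
    is_sex_chrom(chrom) & !is.na(gnomad_af_xy)
  af <- ifelse(use_xy, gnomad_af_xy, gnomad_af)
  pass <- is.na(af) | af <= config$max_maf
  flag <- ifelse(is.na(af), "absent_from_gnomad", "")
  data.frame(pass = pass, flag = flag, stringsAsFactors = FALSE)
}

#' @rdname filter_predicates
#' @param gene_symbol Gene symbols.
#' @export
apply_panel_filter <- function(gene_symbol, config) {
  if (nrow(config$panel) == 0L) stop("gene panel is empty")
  !is.na(gene_symbol) &
    (gene_symbol %in% config$panel$gene | gene_symbol == config$anchor_gene)
}

#' Run the filter cascade for the index case(s)
#'
#' Emits one decision per variant observed with a non-reference, non-missing
#' genotype in each index sample. Filters are evaluated in the fixed order
#' depth, consequence, MAF, panel, and `fail_reasons` lists the failed
#' stages in that order. Depth gating uses the index sample's genotype;
#' family members' genotypes are carried along untouched for the
#' segregation stage. A variant with no annotation row is never silently
#' dropped: its decision is emitted with `retained = FALSE` and fail reason
#' `unannotated`.
#'
#' @param variants Variant data.frame from [read_vcf()] (or equivalent) with
#'   `variant_key`, `gene_symbol`, `consequence`.
#' @param genotypes Genotype data.frame with `sample_id`, `variant_key`,
#'   `zygosity`, `depth`.
#' @param annotations Annotation data.frame from [read_annotation_table()].
#' @param pedigree Pedigree data.frame; rows with `is_index` define the
#'   cases filtered.
#' @param config A [filter_config()].
#' @return A data.frame of filter decisions: `case_id`, `variant_key`,
#'   `gene_symbol`, the four `passed_*` flags, `retained`, `fail_reasons`
#'   (comma-separated, ordered) and `flags`.
#' @export
run_cascade <- function(variants, genotypes, annotations, pedigree, config) {
  index_ids <- pedigree$sample_id[pedigree$is_index]
  out <- lapply(index_ids, function(idx) {
    kar <- pedigree$karyotype[pedigree$sample_id == idx]
    g <- genotypes[genotypes$sample_id == idx &
                     !(genotypes$zygosity %in% c("hom_ref", "missing")), ,
                   drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    v <- variants[match(g$variant_key, variants$variant_key), , drop = FALSE]
    a <- annotations[match(g$variant_key, annotations$variant_key), ,
                     drop = FALSE]
    annotated <- !is.na(a$variant_key)
    consequence <- ifelse(!is.na(v$consequence), v$consequence, a$consequence)
    gene <- ifelse(!is.na(v$gene_symbol), v$gene_symbol, a$gene)

    passed_depth <- apply_depth_filter(g$depth, config)
    passed_consequence <- !is.na(consequence) &
      !(consequence %in% config$excluded_consequences)
    maf <- apply_maf_filter(a$gnomad_af, a$gnomad_af_xy, v$chrom,
                            rep(kar, nrow(g)), config)
    passed_maf <- maf$pass & annotated
    passed_panel <- apply_panel_filter(gene, config)
    retained <- passed_depth & passed_consequence & passed_maf & passed_panel

    fail_reasons <- mapply(function(d, cq, m, p, ann, dep) {
      r <- character()
      if (!d) r <- c(r, if (is.na(dep)) "no_depth" else "low_depth")
      if (!cq) r <- c(r, "consequence")
      if (!m) r <- c(r, if (!ann) "unannotated" else "maf")
      if (!p) r <- c(r, "not_in_panel")
      paste(r, collapse = ",")
    }, passed_depth, passed_consequence, passed_maf, passed_panel,
       annotated, g$depth)

    data.frame(case_id = idx, variant_key = g$variant_key,
               gene_symbol = gene, consequence = consequence,
               zygosity = g$zygosity, depth = g$depth,
               passed_depth = passed_depth,
               passed_consequence = passed_consequence,
               passed_maf = passed_maf, passed_panel = passed_panel,
               retained = retained, fail_reasons = fail_reasons,
               flags = maf$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(case_id = character(), variant_key = character(),
                      gene_symbol = character(), consequence = character(),
                      zygosity = character(), depth = integer(),
                      passed_depth = logical(), passed_consequence = logical(),
                      passed_maf = logical(), passed_panel = logical(),
                      retained = logical(), fail_reasons = character(),
                      flags = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
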