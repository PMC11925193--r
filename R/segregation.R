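parent_carrier_state <- function(parent_id, variant_key, genotypes,
                                 min_depth) {
  if (!nzchar(parent_id)) return("unknown")
  g <- genotypes[genotypes$sample_id == parent_id &
                   genotypes$variant_key == variant_key, , drop = FALSE]
  if (nrow(g) == 0L || g$zygosity[1] == "missing") return("unknown")
  if (g$zygosity[1] %in% c("het", "hom_alt", "hemizygous")) return("carrier")
  # asserting absence requires adequate depth at the site
  if (!is.na(g$depth[1]) && g$depth[1] >= min_depth) return("non_carrier")
  "unknown"
}

#' Classify the inheritance of a variant in an index case
#'
#' Trio logic over the parental genotypes: a carrier parent gives a
#' `maternal`/`paternal` call, both parents carriers give
#' `biparental_ambiguous`, and `de_novo` is only ever emitted when both
#' parents are genotyped reference at adequate read depth — an ungenotyped
#' or low-depth parent always yields `unresolved`, never `de_novo`.
#'
#' @param variant_key Variant key to classify.
#' @param index_id Sample id of the index case (must carry the variant).
#' @param pedigree Pedigree data.frame.
#' @param genotypes Genotype data.frame (`sample_id`, `variant_key`,
#'   `zygosity`, `depth`).
#' @param min_depth Depth required to assert a parent is a non-carrier
#'   (default 20, the cascade's depth convention).
#' @return A one-row data.frame: `variant_key`, `sample_id`, `call`,
#'   `father_observed`, `mother_observed`.
#' @export
call_inheritance <- function(variant_key, index_id, pedigree, genotypes,
                             min_depth = 20L) {
  idx <- pedigree[pedigree$sample_id == index_id, , drop = FALSE]
  if (nrow(idx) != 1L) stop(sprintf("unknown index sample '%s'", index_id))
  fa <- parent_carrier_state(idx$father_id, variant_key, genotypes, min_depth)
  mo <- parent_carrier_state(idx$mother_id, variant_key, genotypes, min_depth)
  call <- if (fa == "carrier" && mo == "carrier") "biparental_ambiguous"
    else if (fa == "carrier") "paternal"
    else if (mo == "carrier") "maternal"
    else if (fa == "non_carrier" && mo == "non_carrier") "de_novo"
    else "unresolved"
  data.frame(variant_key = variant_key, sample_id = index_id, call = call,
             father_observed = fa != "unknown",
             mother_observed = mo != "unknown", stringsAsFactors = FALSE)
}

#' Carrier status of every family member for a variant
#'
#' @param pedigree Pedigree data.frame (one family).
#' @param variant_key Variant key, typically the family's anchor variant.
#' @param genotypes Genotype data.frame.
#' @return A data.frame `sample_id`/`status` with status `carrier`,
#'   `non_carrier` or `unknown`.
#' @export
carrier_status <- function(pedigree, variant_key, genotypes) {
  status <- vapply(pedigree$sample_id, function(sid) {
    g <- genotypes[genotypes$sample_id == sid &
                     genotypes$variant_key == variant_key, , drop = FALSE]
    if (nrow(g) == 0L || g$zygosity[1] == "missing") return("unknown")
    if (g$zygosity[1] %in% c("het", "hom_alt", "hemizygous")) return("carrier")
    "non_carrier"
  }, character(1))
  data.frame(sample_id = pedigree$sample_id, status = unname(status),
             stringsAsFactors = FALSE)
}

#' Co-segregation consistency of an anchor-partner pair within a family
#'
#' Formalises the digenic expectation that disease requires a pathogenic
#' allele in each gene simultaneously: a relative of the index is consistent
#' when carrying both variants implies being affected, and carrying at most
#' one implies being unaffected. Relatives with an unknown affection class
#' or a missing genotype for either variant are not evaluable; relatives in
#' a configurable `partially_affected` class (e.g. mild phenotypes treated
#' as incomplete penetrance rather than contradiction) are excluded from
#' the denominator. The statistic is this package's formalisation of
#' qualitative family-segregation assessment and is labelled as such in
#' reports.
#'
#' @param anchor_key,partner_key Variant keys of the pair.
#' @param pedigree Pedigree data.frame (one family, including the index).
#' @param genotypes Genotype data.frame.
#' @param index_id Sample id of the index case (excluded from evaluation).
#' @param affected_classes Affection classes counted as affected.
#' @param partially_affected Affection classes excluded from `n_evaluable`.
#' @return A list: `anchor_key`, `partner_key`, `n_evaluable`,
#'   `n_consistent`, `consistency` (`NA` when no relative is evaluable) and
#'   `counterexamples` (sample ids violating the expectation).
#' @export
cosegregation_consistency <- function(anchor_key, partner_key, pedigree,
                                      genotypes, index_id,
                                      affected_classes = c(
                                        "severe_DSD", "opposite_sex_DSD",
                                        "mild_DSD", "POI", "other_affected"),
                                      partially_affected = character()) {
  relatives <- pedigree[pedigree$sample_id != index_id, , drop = FALSE]
  anchor <- carrier_status(relatives, anchor_key, genotypes)
  partner <- carrier_status(relatives, partner_key, genotypes)
  n_eval <- 0L; n_cons <- 0L; counterexamples <- character()
  for (i in seq_len(nrow(relatives))) {
    aff_class <- relatives$affection[i]
    if (aff_class %in% c("unknown") || aff_class %in% partially_affected) next
    if (anchor$status[i] == "unknown" || partner$status[i] == "unknown") next
    n_eval <- n_eval + 1L
    both <- anchor$status[i] == "carrier" && partner$status[i] == "carrier"
    affected <- aff_class %in% affected_classes
    consistent <- if (both) affected else !affected
    if (consistent) n_cons <- n_cons + 1L
    else counterexamples <- c(counterexamples, relatives$sample_id[i])
  }
  list(anchor_key = anchor_key, partner_key = partner_key,
       n_evaluable = n_eval, n_consistent = n_cons,
       consistency = if (n_eval > 0L) n_cons / n_eval else NA_real_,
       counterexamples = counterexamples)
}

#' Scan a gene for potential compound heterozygosity in the index
#'
#' Considers every unordered pair of heterozygous variants the index
#' carries in one gene. Phase is inferred from parental transmission only:
#' when the two variants trace to different origins (different parents, or
#' one parental and one de novo) the pair is `confirmed_trans`; two
#' variants from the same parent are in cis and not reported; anything
#' unresolved is `possible`.
#'
#' @param gene Gene symbol to scan.
#' @param variants Variant data.frame with `variant_key` and `gene_symbol`.
#' @param genotypes Genotype data.frame.
#' @param pedigree Pedigree data.frame.
#' @param index_id Index sample id.
#' @param min_depth Depth convention for [call_inheritance()].
#' @return A data.frame `gene`, `key1`, `key2`, `phase`
#'   (`confirmed_trans`/`possible`); zero rows when fewer than two
#'   heterozygous variants or all pairs are in cis.
#' @export
compound_het_scan <- function(gene, variants, genotypes, pedigree, index_id,
                              min_depth = 20L) {
  keys <- variants$variant_key[variants$gene_symbol %in% gene]
  g <- genotypes[genotypes$sample_id == index_id &
                   genotypes$variant_key %in% keys &
                   genotypes$zygosity == "het", , drop = FALSE]
  out <- data.frame(gene = character(), key1 = character(),
                    key2 = character(), phase = character(),
                    stringsAsFactors = FALSE)
  if (nrow(g) < 2L) return(out)
  keys <- sort(g$variant_key)
  calls <- vapply(keys, function(k) {
    call_inheritance(k, index_id, pedigree, genotypes, min_depth)$call
  }, character(1))
  origin <- c(paternal = "P", maternal = "M", de_novo = "D",
              biparental_ambiguous = "?", unresolved = "?")
  for (i in seq_len(length(keys) - 1L)) {
    for (j in seq(i + 1L, length(keys))) {
      o1 <- origin[calls[i]]; o2 <- origin[calls[j]]
      phase <- if (o1 == "?" || o2 == "?" || (o1 == "D" && o2 == "D")) {
        "possible"
      } else if (o1 != o2) {
        "confirmed_trans"
      } else {
        NA_character_  # cis, not reported
      }
      if (!is.na(phase)) {
        out <- rbind(out, data.frame(gene = gene, key1 = keys[i],
                                     key2 = keys[j], phase = phase,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}
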