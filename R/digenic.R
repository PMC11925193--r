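#' Pair-pathogenicity score thresholds
#'
#' Two nested cutoffs govern the interpretation of a pair score: above
#' `disease_causing` (strict, default 0.4575 on hg38) the combination is
#' predicted disease-causing; at or above `confidence_zone` (inclusive,
#' default 0.85) it additionally falls in the 99.9% confidence zone of the
#' predictor and qualifies under criterion 1.
#'
#' @param disease_causing Strict lower cutoff for a disease-causing
#'   prediction.
#' @param confidence_zone Inclusive cutoff for the 99.9% confidence zone.
#' @return A list of class `pair_thresholds`.
#' @export
pair_thresholds <- function(disease_causing = 0.4575, confidence_zone = 0.85) {
  stopifnot(disease_causing > 0, disease_causing < confidence_zone,
            confidence_zone < 1)
  structure(list(disease_causing = disease_causing,
                 confidence_zone = confidence_zone),
            class = "pair_thresholds")
}

#' Classify a pair score against the threshold zones
#'
#' Boundary semantics follow the predictor's definitions: disease-causing
#' requires a score strictly above the lower cutoff ("above 0.4575"), the
#' confidence zone is inclusive ("\eqn{\ge} 0.85"). A missing score (no
#' prediction, `ND`) is in neither zone and is flagged.
#'
#' @param score Numeric scores in `[0,1]`, `NA` for no prediction.
#' @param thresholds A [pair_thresholds()].
#' @return A data.frame with `disease_causing`, `in_confidence_zone`, `flag`.
#' @export
classify_pair_zone <- function(score, thresholds = pair_thresholds()) {
  dc <- !is.na(score) & score > thresholds$disease_causing
  cz <- !is.na(score) & score >= thresholds$confidence_zone
  data.frame(disease_causing = dc, in_confidence_zone = cz,
             flag = ifelse(is.na(score), "ND", ""),
             stringsAsFactors = FALSE)
}

#' Build anchor-partner variant pairs
#'
#' Forms one pair per retained candidate against the family's anchor
#' variant and attaches the ingested pair scores. Candidates without a
#' score row get a missing score. A non-scorable anchor (symbolic or
#' structural allele, or one the external predictor cannot assess) yields
#' no pairs and the case-level flag `anchor_not_pairable`.
#'
#' @param anchor_key Variant key of the anchor variant.
#' @param candidate_keys Variant keys of the filter-cascade survivors
#'   (excluding the anchor itself).
#' @param pair_scores Pair score data.frame from [read_pair_scores()].
#' @param anchor_scorable Logical; `FALSE` for symbolic/structural anchors.
#' @return A data.frame of pairs (`anchor_key`, `partner_key`, `score`,
#'   `effect_class`) with attribute `anchor_not_pairable` set accordingly.
#' @export
build_pairs <- function(anchor_key, candidate_keys, pair_scores,
                        anchor_scorable = TRUE) {
  empty <- data.frame(anchor_key = character(), partner_key = character(),
                      score = numeric(), effect_class = character(),
                      stringsAsFactors = FALSE)
  if (!anchor_scorable) {
    attr(empty, "anchor_not_pairable") <- TRUE
    return(empty)
  }
  candidate_keys <- setdiff(candidate_keys, anchor_key)
  if (length(candidate_keys) == 0L) {
    attr(empty, "anchor_not_pairable") <- FALSE
    return(empty)
  }
  ps <- pair_scores[pair_scores$anchor_key == anchor_key &
                      pair_scores$partner_key %in% candidate_keys, ,
                    drop = FALSE]
  if (anyDuplicated(ps$partner_key)) {
    stop(sprintf("duplicate pair score rows for partner %s",
                 ps$partner_key[duplicated(ps$partner_key)][1]))
  }
  m <- match(candidate_keys, ps$partner_key)
  out <- data.frame(
    anchor_key = anchor_key, partner_key = candidate_keys,
    score = ps$score[m],
    effect_class = ifelse(is.na(m), "missing", ps$effect_class[m]),
    stringsAsFactors = FALSE)
  attr(out, "anchor_not_pairable") <- FALSE
  out
}

#' Select candidate pairs by the two-criterion rule
#'
#' A pair is retained when it meets criterion 1 (pair score in the
#' confidence zone) or criterion 2 (the partner variant's own pathogenicity
#' consensus from [criterion2_eval()]), and the partner is not rejected for
#' lack of phenotype relevance. The deny list stands in for the manual
#' literature/phenotype review: genes or variant keys listed there are
#' marked `phenotype_rejected` whatever the criteria say.
#'
#' @param pairs Pair data.frame from [build_pairs()].
#' @param consensus Consensus data.frame from [criterion2_eval()] covering
#'   every partner key.
#' @param deny_list Character vector of gene symbols and/or variant keys to
#'   reject (default empty).
#' @param gene_of Optional named character vector mapping variant keys to
#'   gene symbols, used to apply gene-level deny entries.
#' @param thresholds A [pair_thresholds()].
#' @return A pair-decision data.frame adding `disease_causing`,
#'   `in_confidence_zone`, `criterion1`, `criterion2`, `phenotype_rejected`,
#'   `retained` and a human-readable `rationale`.
#' @export
select_candidates <- function(pairs, consensus, deny_list = character(),
                              gene_of = NULL,
                              thresholds = pair_thresholds()) {
  zone <- classify_pair_zone(pairs$score, thresholds)
  m <- match(pairs$partner_key, consensus$variant_key)
  if (nrow(pairs) && any(is.na(m))) {
    stop("consensus results missing for some partner variants")
  }
  criterion1 <- zone$in_confidence_zone
  criterion2 <- if (nrow(pairs)) consensus$criterion2[m] else logical()
  denied <- pairs$partner_key %in% deny_list
  if (!is.null(gene_of) && nrow(pairs)) {
    denied <- denied | unname(gene_of[pairs$partner_key]) %in% deny_list
  }
  retained <- (criterion1 | criterion2) & !denied
  rationale <- ifelse(denied, "rejected: no phenotype association",
    ifelse(criterion1 & criterion2, "criterion 1 (confidence zone) and criterion 2 (consensus)",
      ifelse(criterion1, "criterion 1 (pair score in confidence zone)",
        ifelse(criterion2, "criterion 2 (ACMG/tool consensus)",
               "neither criterion met"))))
  out <- data.frame(pairs, disease_causing = zone$disease_causing,
                    in_confidence_zone = zone$in_confidence_zone,
                    score_flag = zone$flag,
                    criterion1 = criterion1, criterion2 = criterion2,
                    phenotype_rejected = denied, retained = retained,
                    rationale = rationale, stringsAsFactors = FALSE)
  attr(out, "anchor_not_pairable") <- isTRUE(attr(pairs, "anchor_not_pairable"))
  out
}

#' Tally digenic effect classes among retained pairs
#'
#' @param decisions Pair-decision data.frame from [select_candidates()]
#'   (possibly row-bound across cases).
#' @return A list with `counts` (named integer vector over the effect class
#'   vocabulary) and `fractions` (over retained pairs; `NaN` when none).
#' @export
effect_class_summary <- function(decisions) {
  ret <- decisions[decisions$retained, , drop = FALSE]
  counts <- vapply(effect_class_levels(),
                   function(cl) sum(ret$effect_class == cl), integer(1))
  list(counts = counts, fractions = counts / nrow(ret))
}

#' Deterministic surrogate pair scorer (synthetic runs only)
#'
#' A clearly-labelled stand-in for the external trained pair-pathogenicity
#' predictor, for use on synthetic cohorts where no real scores exist. It is
#' a fixed calibrated logistic over partner CADD, partner allele frequency,
#' panel category and anchor consequence severity — NOT a reimplementation
#' of the published random-forest model, and results carry the metadata
#' attribute `scorer = "surrogate_logistic_v1"` to make that visible.
#'
#' @param cadd_phred Partner CADD Phred scores.
#' @param gnomad_af Partner allele frequencies (`NA` treated as 1e-6).
#' @param panel_category Panel category of the partner gene (`DSD`, `SF1`,
#'   `both`).
#' @param anchor_consequence Consequence class of the anchor variant.
#' @return Numeric scores in `[0,1]` with attribute `scorer`.
#' @export
surrogate_pair_score <- function(cadd_phred, gnomad_af, panel_category,
                                 anchor_consequence) {
  severity <- c(missense = 1, inframe_indel = 1, splice_site = 2,
                frameshift = 2, stop_gained = 2, start_lost = 2,
                duplication = 0.5, structural_deletion = 0.5,
                synonymous = 0, other = 0.5)
  catw <- c(DSD = 1, SF1 = 1, both = 1.5)
  af <- ifelse(is.na(gnomad_af) | gnomad_af <= 0, 1e-6, gnomad_af)
  cadd <- ifelse(is.na(cadd_phred), 0, cadd_phred)
  lin <- -6 + 0.22 * cadd - 0.45 * log10(af) +
    0.8 * unname(severity[anchor_consequence]) +
    0.6 * unname(catw[panel_category])
  out <- stats::plogis(lin)
  attr(out, "scorer") <- "surrogate_logistic_v1"
  out
}
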