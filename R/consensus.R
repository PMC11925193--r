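#' Count pathogenic-leaning votes among the nine in-silico tools
#'
#' A tool votes for the variant when its call is `pathogenic_like` or
#' `uncertain` — the qualifying verdicts span pathogenic, likely pathogenic
#' and VUS, so an uncertain call counts toward the vote. Missing calls
#' reduce the informative count but the vote denominator stays fixed at
#' nine (a missing tool counts against the variant).
#'
#' @param annotations Annotation data.frame with the nine `tool_*` columns.
#' @return A data.frame with `variant_key`, `n_informative` and
#'   `n_pathogenic_like`.
#' @export
count_pathogenic_votes <- function(annotations) {
  cols <- paste0("tool_", tool_names())
  calls <- as.matrix(annotations[cols])
  qualifying <- matrix(calls %in% c("pathogenic_like", "uncertain"),
                       nrow = nrow(calls))
  data.frame(
    variant_key = annotations$variant_key,
    n_informative = rowSums(calls != "missing"),
    n_pathogenic_like = rowSums(qualifying),
    stringsAsFactors = FALSE)
}

#' Resolve the more pathogenic of two platform ACMG classes
#'
#' The two classification platforms may disagree; the consensus takes the
#' more pathogenic class under the ordering B < LB < VUS < LP < P. When one
#' platform has no class, the other is used; when both are missing the
#' result is `missing`.
#'
#' @param varsome,franklin ACMG class strings (`B`, `LB`, `VUS`, `LP`, `P`,
#'   `missing`).
#' @return Character vector of resolved classes.
#' @export
acmg_best_class <- function(varsome, franklin) {
  rank <- stats::setNames(seq_along(acmg_levels()), acmg_levels())
  rank <- c(rank, missing = 0L)
  best <- pmax(rank[varsome], rank[franklin])
  out <- ifelse(best == 0L, "missing", acmg_levels()[best])
  unname(out)
}

#' Evaluate the per-variant pathogenicity consensus (criterion 2)
#'
#' Criterion 2 of candidate selection retains a variant on its own merits,
#' regardless of any pair-score prediction: it passes when its resolved ACMG
#' class is VUS, likely pathogenic or pathogenic, or when at least
#' `min_votes` of the nine in-silico tools call it pathogenic-leaning
#' (pathogenic, likely pathogenic or VUS).
#'
#' @param annotations Annotation data.frame.
#' @param min_votes Minimum qualifying tool votes (default 7 of 9).
#' @return A data.frame with `variant_key`, `n_informative`,
#'   `n_pathogenic_like`, `vote_pass`, `acmg_best`, `acmg_pass` and
#'   `criterion2`.
#' @export
criterion2_eval <- function(annotations, min_votes = 7L) {
  votes <- count_pathogenic_votes(annotations)
  votes$vote_pass <- votes$n_pathogenic_like >= min_votes
  votes$acmg_best <- acmg_best_class(annotations$acmg_varsome,
                                     annotations$acmg_franklin)
  votes$acmg_pass <- votes$acmg_best %in% c("VUS", "LP", "P")
  votes$criterion2 <- votes$acmg_pass | votes$vote_pass
  votes
}
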