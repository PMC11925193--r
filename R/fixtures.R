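fixture_path <- function(file) {
  system.file("extdata", file, package = "oligotrio", mustWork = TRUE)
}

#' Default DSD/SF-1 gene panel
#'
#' The packaged panel bundles the anchor gene plus every partner gene of
#' the cohort fixture (the full published DSD/SF-1 panel is not reprinted
#' in the source tables, so this default covers the genes with reported
#' candidate variants; users supply their own panel for real screens).
#'
#' @return A panel data.frame (`gene`, `category`).
#' @export
default_panel <- function() {
  read_gene_panel(fixture_path("default_panel.tsv"))
}

fixture_anchor_key <- function(hgvs_c) {
  paste(default_anchor_gene(), hgvs_c, sep = ":")
}

#' Load the packaged DSD cohort fixture
#'
#' A transcription of the published per-case tables of an anchor-gene
#' (NR5A1/SF-1) oligogenicity cohort: 29 index cases, their anchor
#' variants, and 70 additional variant rows with pair scores, platform ACMG
#' classes and CADD scores. Variant identity is gene + HGVS-c (genomic
#' coordinates are not printed in the source tables), so keys look like
#' `"GLI3:c.2179G>A"`. Cases whose anchor could not be paired by the
#' external predictor (a whole-gene deletion, a homozygous anchor, a large
#' duplication) carry `anchor_pairable = FALSE` with the reason in
#' `anchor_flag`.
#'
#' @return A list: `cases`, `variants`, `annotations` (sidecar-shaped, the
#'   nine tool calls all missing since the source prints only ACMG and
#'   CADD), `pair_scores`, `panel`.
#' @export
load_fixture_cohort <- function() {
  cases <- utils::read.delim(fixture_path("dsd_cohort_cases.tsv"),
                             stringsAsFactors = FALSE)
  cases$anchor_key <- fixture_anchor_key(cases$anchor_hgvs_c)
  cases$anchor_flag[is.na(cases$anchor_flag)] <- ""
  variants <- utils::read.delim(fixture_path("dsd_cohort_variants.tsv"),
                                stringsAsFactors = FALSE,
                                na.strings = c("", "NA", "ND"))
  variants$variant_key <- paste(variants$gene, variants$hgvs_c, sep = ":")
  variants$score <- as.numeric(variants$score)
  variants$effect_class[is.na(variants$effect_class)] <- "missing"

  ann <- data.frame(variant_key = unique(variants$variant_key),
                    stringsAsFactors = FALSE)
  m <- match(ann$variant_key, variants$variant_key)
  ann$gene <- variants$gene[m]
  ann$consequence <- "missense"  # source rows are coding non-synonymous
  ann$gnomad_af <- variants$gnomad_af[m]
  ann$gnomad_af_xy <- NA_real_
  ann$cadd_phred <- variants$cadd[m]
  for (col in paste0("tool_", tool_names())) ann[[col]] <- "missing"
  ann$acmg_varsome <- variants$acmg_varsome[m]
  ann$acmg_franklin <- variants$acmg_franklin[m]
  ann$clinvar_hgmd <- FALSE

  anchor_m <- match(variants$case_id, cases$case_id)
  pair_scores <- data.frame(
    anchor_key = cases$anchor_key[anchor_m],
    partner_key = variants$variant_key,
    score = variants$score,
    effect_class = variants$effect_class,
    stringsAsFactors = FALSE)

  list(cases = cases, variants = variants, annotations = ann,
       pair_scores = pair_scores, panel = default_panel())
}

#' Run the candidate-selection pipeline over the packaged fixture
#'
#' The fixture rows are already filter-cascade survivors (the source tables
#' print post-filter candidates only), so this runs the pairing and
#' two-criterion selection per case: consensus over ACMG classes, pair
#' construction against each case's anchor, zone classification and
#' retention. Cases with a non-pairable anchor contribute their variant
#' rows with `retained = FALSE` and the `anchor_not_pairable` flag so that
#' no row is silently dropped.
#'
#' @param fixture A fixture list from [load_fixture_cohort()] (loaded
#'   afresh when omitted).
#' @param thresholds A [pair_thresholds()].
#' @return A case-results data.frame, one row per (case, variant), with the
#'   pair decision columns plus `case_id`, `family_id`, `gene_symbol`,
#'   `cadd_phred` and `case_flag`.
#' @export
run_fixture_pipeline <- function(fixture = load_fixture_cohort(),
                                 thresholds = pair_thresholds()) {
  consensus <- criterion2_eval(fixture$annotations)
  out <- lapply(seq_len(nrow(fixture$cases)), function(i) {
    cs <- fixture$cases[i, ]
    rows <- fixture$variants[fixture$variants$case_id == cs$case_id, ,
                             drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    pairs <- build_pairs(cs$anchor_key, rows$variant_key,
                         fixture$pair_scores,
                         anchor_scorable = isTRUE(cs$anchor_pairable))
    if (isTRUE(attr(pairs, "anchor_not_pairable"))) {
      zone <- classify_pair_zone(rows$score, thresholds)
      c2 <- consensus$criterion2[match(rows$variant_key,
                                       consensus$variant_key)]
      return(data.frame(
        case_id = cs$case_id, family_id = cs$family_id,
        gene_symbol = rows$gene, variant_key = rows$variant_key,
        score = rows$score, effect_class = rows$effect_class,
        disease_causing = zone$disease_causing,
        in_confidence_zone = zone$in_confidence_zone,
        criterion1 = zone$in_confidence_zone, criterion2 = c2,
        phenotype_rejected = FALSE, retained = FALSE,
        rationale = "anchor not pairable: no oligogenic combination testable",
        cadd_phred = rows$cadd, case_flag = cs$anchor_flag,
        stringsAsFactors = FALSE))
    }
    dec <- select_candidates(pairs, consensus, thresholds = thresholds)
    m <- match(dec$partner_key, rows$variant_key)
    data.frame(
      case_id = cs$case_id, family_id = cs$family_id,
      gene_symbol = rows$gene[m], variant_key = dec$partner_key,
      score = dec$score, effect_class = dec$effect_class,
      disease_causing = dec$disease_causing,
      in_confidence_zone = dec$in_confidence_zone,
      criterion1 = dec$criterion1, criterion2 = dec$criterion2,
      phenotype_rejected = dec$phenotype_rejected, retained = dec$retained,
      rationale = dec$rationale, cadd_phred = rows$cadd[m],
      case_flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

model_trio <- function(family_id, members) {
  do.call(rbind, lapply(members, function(m) {
    data.frame(sample_id = m$id, family_id = family_id,
               father_id = if (is.null(m$father)) "" else m$father,
               mother_id = if (is.null(m$mother)) "" else m$mother,
               karyotype = m$karyotype, affection = m$affection,
               phenotype_notes = "", is_index = isTRUE(m$index),
               stringsAsFactors = FALSE)
  }))
}

model_genotypes <- function(samples, carriers_by_key, depth = 30L) {
  do.call(rbind, lapply(names(carriers_by_key), function(k) {
    data.frame(sample_id = samples,
               variant_key = k,
               zygosity = ifelse(samples %in% carriers_by_key[[k]],
                                 "het", "hom_ref"),
               depth = depth, stringsAsFactors = FALSE)
  }))
}

#' Family fixtures for the five published model cases
#'
#' Hand-encoded pedigrees and genotypes reproducing the five worked family
#' analyses of the source cohort: (1) a paternal anchor with two de novo
#' partner variants; (2) a maternal anchor in two affected siblings with
#' three paternal partner variants and two de novo modifier variants in one
#' sibling; (3) a de novo anchor with two de novo partners; (4) a maternal
#' anchor with two paternal partners; (5) a maternal anchor with four
#' paternal and two de novo partners forming a compound-heterozygous FLNB
#' pair. All genotypes are encoded at depth 30 (complete genotyping).
#'
#' @return A named list (`case_18`, `case_12`, `case_14`, `case_13`,
#'   `case_9`); each element holds `pedigree`, `genotypes`, `anchor_key`,
#'   `index_id` and `expected` (named inheritance calls).
#' @export
fixture_model_pedigrees <- function() {
  anchor <- fixture_anchor_key
  out <- list()

  # model case 1 (index 18): paternal anchor, AXIN1/DKK1 de novo
  ped <- model_trio("F18", list(
    list(id = "18_fa", karyotype = "46,XY", affection = "asymptomatic"),
    list(id = "18_mo", karyotype = "46,XX", affection = "asymptomatic"),
    list(id = "18_in", father = "18_fa", mother = "18_mo",
         karyotype = "46,XY", affection = "severe_DSD", index = TRUE)))
  gk <- list()
  gk[[anchor("c.937C>T")]] <- c("18_fa", "18_in")
  gk[["AXIN1:c.1485C>G"]] <- "18_in"
  gk[["DKK1:c.470G>T"]] <- "18_in"
  out$case_18 <- list(
    pedigree = ped, genotypes = model_genotypes(ped$sample_id, gk),
    anchor_key = anchor("c.937C>T"), index_id = "18_in",
    expected = c(stats::setNames("paternal", anchor("c.937C>T")),
                 "AXIN1:c.1485C>G" = "de_novo", "DKK1:c.470G>T" = "de_novo"))

  # model case 2 (index 12): maternal anchor; GLI3/APC/PKD1 paternal in
  # both siblings; two SYNM variants de novo in the index sibling only
  ped <- model_trio("F12", list(
    list(id = "12_fa", karyotype = "46,XY", affection = "asymptomatic"),
    list(id = "12_mo", karyotype = "46,XX", affection = "asymptomatic"),
    list(id = "12_in", father = "12_fa", mother = "12_mo",
         karyotype = "46,XY", affection = "opposite_sex_DSD", index = TRUE),
    list(id = "12_sib", father = "12_fa", mother = "12_mo",
         karyotype = "46,XY", affection = "severe_DSD")))
  gk <- list()
  gk[[anchor("c.217T>A")]] <- c("12_mo", "12_in", "12_sib")
  for (k in c("GLI3:c.2179G>A", "APC:c.7514G>A", "PKD1:c.12436G>A")) {
    gk[[k]] <- c("12_fa", "12_in", "12_sib")
  }
  gk[["SYNM:c.361C>A"]] <- "12_in"
  gk[["SYNM:c.368C>T"]] <- "12_in"
  out$case_12 <- list(
    pedigree = ped, genotypes = model_genotypes(ped$sample_id, gk),
    anchor_key = anchor("c.217T>A"), index_id = "12_in",
    expected = c(stats::setNames("maternal", anchor("c.217T>A")),
                 "GLI3:c.2179G>A" = "paternal", "APC:c.7514G>A" = "paternal",
                 "PKD1:c.12436G>A" = "paternal",
                 "SYNM:c.361C>A" = "de_novo", "SYNM:c.368C>T" = "de_novo"))

  # model case 3 (index 14): de novo anchor; SPRY4/TBCE de novo
  ped <- model_trio("F14", list(
    list(id = "14_fa", karyotype = "46,XY", affection = "asymptomatic"),
    list(id = "14_mo", karyotype = "46,XX", affection = "asymptomatic"),
    list(id = "14_in", father = "14_fa", mother = "14_mo",
         karyotype = "46,XY", affection = "severe_DSD", index = TRUE)))
  gk <- list()
  gk[[anchor("c.937C>T")]] <- "14_in"
  gk[["SPRY4:c.55C>G"]] <- "14_in"
  gk[["TBCE:c.214C>T"]] <- "14_in"
  out$case_14 <- list(
    pedigree = ped, genotypes = model_genotypes(ped$sample_id, gk),
    anchor_key = anchor("c.937C>T"), index_id = "14_in",
    expected = c(stats::setNames("de_novo", anchor("c.937C>T")),
                 "SPRY4:c.55C>G" = "de_novo", "TBCE:c.214C>T" = "de_novo"))

  # model case 4 (index 13): maternal anchor; CBX2/GLI3 paternal
  ped <- model_trio("F13", list(
    list(id = "13_fa", karyotype = "46,XY", affection = "asymptomatic"),
    list(id = "13_mo", karyotype = "46,XX", affection = "asymptomatic"),
    list(id = "13_in", father = "13_fa", mother = "13_mo",
         karyotype = "46,XY", affection = "severe_DSD", index = TRUE)))
  gk <- list()
  gk[[anchor("c.40C>T")]] <- c("13_mo", "13_in")
  gk[["CBX2:c.849G>T"]] <- c("13_fa", "13_in")
  gk[["GLI3:c.2179G>A"]] <- c("13_fa", "13_in")
  out$case_13 <- list(
    pedigree = ped, genotypes = model_genotypes(ped$sample_id, gk),
    anchor_key = anchor("c.40C>T"), index_id = "13_in",
    expected = c(stats::setNames("maternal", anchor("c.40C>T")),
                 "CBX2:c.849G>T" = "paternal", "GLI3:c.2179G>A" = "paternal"))

  # model case 5 (index 9): maternal anchor; PDGFRA/PKD1/CITED2/FLNB(4233)
  # paternal; TBCE and FLNB(6017) de novo -> compound het FLNB in trans
  ped <- model_trio("F09", list(
    list(id = "9_fa", karyotype = "46,XY", affection = "asymptomatic"),
    list(id = "9_mo", karyotype = "46,XX", affection = "asymptomatic"),
    list(id = "9_in", father = "9_fa", mother = "9_mo",
         karyotype = "46,XY", affection = "opposite_sex_DSD", index = TRUE)))
  gk <- list()
  gk[[anchor("c.902G>A")]] <- c("9_mo", "9_in")
  for (k in c("PDGFRA:c.1285G>A", "PKD1:c.6598C>T", "CITED2:c.117_119del",
              "FLNB:c.4233C>G")) {
    gk[[k]] <- c("9_fa", "9_in")
  }
  gk[["TBCE:c.214C>T"]] <- "9_in"
  gk[["FLNB:c.6017A>G"]] <- "9_in"
  out$case_9 <- list(
    pedigree = ped, genotypes = model_genotypes(ped$sample_id, gk),
    anchor_key = anchor("c.902G>A"), index_id = "9_in",
    expected = c(stats::setNames("maternal", anchor("c.902G>A")),
                 "PDGFRA:c.1285G>A" = "paternal",
                 "PKD1:c.6598C>T" = "paternal",
                 "CITED2:c.117_119del" = "paternal",
                 "FLNB:c.4233C>G" = "paternal",
                 "TBCE:c.214C>T" = "de_novo", "FLNB:c.6017A>G" = "de_novo"))
  out
}
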