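# shared builders for in-code fixtures

mk_annotation <- function(variant_key, gene = "GLI3",
                          consequence = "missense", gnomad_af = NA_real_,
                          gnomad_af_xy = NA_real_, cadd = 25,
                          tools = rep("missing", 9),
                          acmg_varsome = "missing",
                          acmg_franklin = "missing") {
  stopifnot(length(tools) == 9)
  df <- data.frame(variant_key = variant_key, gene = gene,
                   consequence = consequence, gnomad_af = gnomad_af,
                   gnomad_af_xy = gnomad_af_xy, cadd_phred = cadd,
                   stringsAsFactors = FALSE)
  tl <- as.data.frame(as.list(stats::setNames(
    tools, paste0("tool_", tool_names()))), stringsAsFactors = FALSE)
  df <- cbind(df, tl)
  df$acmg_varsome <- acmg_varsome
  df$acmg_franklin <- acmg_franklin
  df$clinvar_hgmd <- FALSE
  df
}

mk_trio_ped <- function(fam = "F1", fa = "fa", mo = "mo", idx = "idx",
                        idx_affection = "severe_DSD",
                        fa_affection = "asymptomatic",
                        mo_affection = "asymptomatic") {
  data.frame(
    sample_id = c(fa, mo, idx), family_id = fam,
    father_id = c("", "", fa), mother_id = c("", "", mo),
    karyotype = c("46,XY", "46,XX", "46,XY"),
    affection = c(fa_affection, mo_affection, idx_affection),
    phenotype_notes = "", is_index = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

mk_genotype <- function(sample_id, variant_key, zygosity, depth = 30L) {
  data.frame(sample_id = sample_id, variant_key = variant_key,
             zygosity = zygosity, depth = depth, stringsAsFactors = FALSE)
}

write_test_vcf <- function(body_lines, samples = c("fa", "mo", "idx"),
                           contigs = c("chr1", "chrX"),
                           format_defs = TRUE) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    if (format_defs) c(
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, info = ".", format = "GT:DP",
                    ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, format, ...),
        collapse = "\t")
}
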