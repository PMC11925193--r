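#' Read a multi-sample VCF into the shared variant/genotype model
#'
#' Parses a VCF v4.2 file with [VariantAnnotation::readVcf()], decomposes
#' multiallelic records into one alternate allele per variant, trims shared
#' REF/ALT bases via [normalize_variant()], and maps per-sample genotype
#' calls to zygosity states using each sample's karyotype from the pedigree.
#' Depth is taken per sample from FORMAT `DP`, else the sum of FORMAT `AD`,
#' else INFO `DP`. Optional INFO fields `GENE` and `CSQ` populate the gene
#' symbol and consequence; when absent they are left `NA` and may be joined
#' later from the annotation sidecar.
#'
#' @param path Path to a VCF file.
#' @param pedigree A pedigree data.frame from [read_ped()]; every sample in
#'   the VCF header must appear in it.
#' @return A list with elements `variants` (one row per decomposed alternate
#'   allele: `chrom`, `pos`, `ref`, `alt`, `gene_symbol`, `consequence`,
#'   `variant_key`, `scorable`) and `genotypes` (`sample_id`, `variant_key`,
#'   `zygosity`, `dosage`, `depth`, `flag`).
#' @export
read_vcf <- function(path, pedigree) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop(sprintf("malformed VCF '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  samples <- colnames(vcf)
  unknown <- setdiff(samples, pedigree$sample_id)
  if (length(unknown)) {
    stop(sprintf("sample(s) not in pedigree: %s",
                 paste(unknown, collapse = ", ")))
  }
  kar <- stats::setNames(pedigree$karyotype, pedigree$sample_id)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  if (!methods::is(alt_list, "CharacterList")) {
    alt_list <- methods::as(alt_list, "CharacterList")
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  gmat <- VariantAnnotation::geno(vcf)
  dp <- if ("DP" %in% names(gmat)) gmat$DP else NULL
  ad <- if ("AD" %in% names(gmat)) gmat$AD else NULL
  info <- VariantAnnotation::info(vcf)
  info_dp <- if ("DP" %in% colnames(info)) info$DP else rep(NA_integer_, length(rr))
  gene <- if ("GENE" %in% colnames(info)) as.character(info$GENE) else rep(NA_character_, length(rr))
  csq <- if ("CSQ" %in% colnames(info)) as.character(info$CSQ) else rep(NA_character_, length(rr))

  var_rows <- list(); gt_rows <- list(); k <- 0L
  for (i in seq_along(rr)) {
    alts <- alt_list[[i]]
    n_alt <- length(alts)
    for (a in seq_len(n_alt)) {
      altx <- alts[a]
      symbolic <- is_symbolic_allele(altx)
      norm <- if (symbolic) {
        data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = altx,
                   variant_key = paste(chrom[i], pos[i], ref[i], altx, sep = ":"),
                   stringsAsFactors = FALSE)
      } else {
        normalize_variant(chrom[i], pos[i], ref[i], altx)
      }
      k <- k + 1L
      var_rows[[k]] <- data.frame(
        norm, gene_symbol = gene[i], consequence = csq[i],
        scorable = !symbolic, stringsAsFactors = FALSE)
      # per-sample genotypes for this alternate allele
      dosage <- integer(length(samples)); ploidy <- integer(length(samples))
      depth <- integer(length(samples))
      for (s in seq_along(samples)) {
        alleles <- strsplit(gt[i, s], "[/|]")[[1]]
        if (length(alleles) == 0L || any(alleles == ".")) {
          dosage[s] <- NA_integer_; ploidy[s] <- length(alleles)
        } else {
          ia <- suppressWarnings(as.integer(alleles))
          dosage[s] <- sum(ia == a)
          ploidy[s] <- length(ia)
        }
        d <- NA_integer_
        if (!is.null(dp) && !is.na(dp[i, s])) {
          d <- as.integer(dp[i, s])
        } else if (!is.null(ad)) {
          adv <- ad[i, s][[1]]
          if (!all(is.na(adv))) d <- as.integer(sum(adv, na.rm = TRUE))
        }
        if (is.na(d)) d <- as.integer(info_dp[i])
        depth[s] <- d
      }
      zz <- genotype_to_zygosity(dosage, ploidy, rep(norm$chrom, length(samples)),
                                 unname(kar[samples]), depth)
      gt_rows[[k]] <- data.frame(
        sample_id = samples, variant_key = norm$variant_key,
        zygosity = zz$zygosity, dosage = dosage, depth = depth,
        flag = zz$flag, stringsAsFactors = FALSE)
    }
  }
  variants <- if (k) do.call(rbind, var_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), variant_key = character(),
               gene_symbol = character(), consequence = character(),
               scorable = logical(), stringsAsFactors = FALSE)
  genotypes <- if (k) do.call(rbind, gt_rows) else
    data.frame(sample_id = character(), variant_key = character(),
               zygosity = character(), dosage = integer(), depth = integer(),
               flag = character(), stringsAsFactors = FALSE)
  variants <- variants[!duplicated(variants$variant_key), , drop = FALSE]
  rownames(variants) <- NULL; rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}

ped_sex_to_karyotype <- function(sex) {
  ifelse(sex == "1", "46,XY", ifelse(sex == "2", "46,XX", "other"))
}

#' Read a pedigree (PED) file
#'
#' Accepts the standard six whitespace-delimited columns (family, sample,
#' father, mother, sex, phenotype). A header line beginning with `#` may
#' declare additional columns `karyotype`, `affection`, `phenotype_notes`
#' and `is_index`. When `karyotype` is absent it is inferred from the sex
#' column; when `affection` is absent, phenotype 2 maps to `other_affected`,
#' 1 to `asymptomatic` and anything else to `unknown`. When `is_index` is
#' absent, within each family the affected individuals with at least one
#' parent recorded are marked index (first such individual if several).
#' A parent id that refers to no individual in the file is cleared with a
#' warning; duplicate sample ids and cyclic parentage are errors.
#'
#' @param path Path to the PED file.
#' @return A data.frame with one row per individual: `sample_id`,
#'   `family_id`, `father_id`, `mother_id`, `karyotype`, `affection`,
#'   `phenotype_notes`, `is_index`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(trimws(sub("^#+\\s*", "", lines[1])), "[\t ]+")[[1]]
    lines <- lines[-1]
  }
  base_cols <- c("family_id", "sample_id", "father_id", "mother_id",
                 "sex", "phenotype")
  if (is.null(header)) header <- base_cols
  if (length(header) < 6L) stop("PED header must declare at least 6 columns")
  header[1:6] <- base_cols
  fields <- strsplit(lines, "\t")
  # fall back to whitespace splitting for space-delimited files
  if (length(fields) && length(fields[[1]]) < length(header)) {
    fields <- strsplit(lines, "[\t ]+")
  }
  bad <- which(vapply(fields, length, 1L) < 6L)
  if (length(bad)) stop(sprintf("PED row %d has fewer than 6 columns", bad[1]))
  mat <- do.call(rbind, lapply(fields, function(f) f[seq_along(header)]))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header

  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample id in PED: %s",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  clear <- function(x) ifelse(is.na(x) | x %in% c("0", ".", ""), "", x)
  df$father_id <- clear(df$father_id)
  df$mother_id <- clear(df$mother_id)
  for (col in c("father_id", "mother_id")) {
    orphan <- nzchar(df[[col]]) & !(df[[col]] %in% df$sample_id)
    if (any(orphan)) {
      warning(sprintf("unknown %s id(s) %s; parent flagged unknown",
                      sub("_id", "", col),
                      paste(unique(df[[col]][orphan]), collapse = ", ")))
      df[[col]][orphan] <- ""
    }
  }
  # cycle detection over parent edges
  parent_of <- function(id) {
    r <- df[df$sample_id == id, ]
    c(r$father_id, r$mother_id)
  }
  for (id in df$sample_id) {
    frontier <- id; seen <- character()
    while (length(frontier)) {
      seen <- c(seen, frontier)
      frontier <- unique(unlist(lapply(frontier, parent_of)))
      frontier <- frontier[nzchar(frontier)]
      if (any(frontier %in% seen)) stop("cyclic parentage in PED")
    }
  }
  df$karyotype <- if ("karyotype" %in% names(df)) df$karyotype else
    ped_sex_to_karyotype(df$sex)
  df$affection <- if ("affection" %in% names(df)) {
    match_arg_vec(df$affection, affection_levels(), "affection")
  } else {
    ifelse(df$phenotype == "2", "other_affected",
           ifelse(df$phenotype == "1", "asymptomatic", "unknown"))
  }
  df$phenotype_notes <- if ("phenotype_notes" %in% names(df))
    df$phenotype_notes else ""
  if ("is_index" %in% names(df)) {
    df$is_index <- df$is_index %in% c("1", "TRUE", "true", "yes")
  } else {
    df$is_index <- FALSE
    affected <- !(df$affection %in% c("asymptomatic", "unknown"))
    for (fam in unique(df$family_id)) {
      sel <- df$family_id == fam & affected &
        (nzchar(df$father_id) | nzchar(df$mother_id))
      if (!any(sel)) sel <- df$family_id == fam & affected
      if (any(sel)) df$is_index[which(sel)[1]] <- TRUE
    }
  }
  df[c("sample_id", "family_id", "father_id", "mother_id", "karyotype",
       "affection", "phenotype_notes", "is_index")]
}

#' Write a pedigree data.frame to a headered PED file
#' @param pedigree Data.frame from [read_ped()] or built in code.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(pedigree, path) {
  sex <- ifelse(pedigree$karyotype == "46,XY", "1",
                ifelse(pedigree$karyotype == "46,XX", "2", "0"))
  phen <- ifelse(pedigree$affection %in% c("asymptomatic"), "1",
                 ifelse(pedigree$affection == "unknown", "0", "2"))
  out <- data.frame(
    family_id = pedigree$family_id, sample_id = pedigree$sample_id,
    father_id = ifelse(nzchar(pedigree$father_id), pedigree$father_id, "0"),
    mother_id = ifelse(nzchar(pedigree$mother_id), pedigree$mother_id, "0"),
    sex = sex, phenotype = phen, karyotype = pedigree$karyotype,
    affection = pedigree$affection,
    is_index = as.integer(pedigree$is_index), stringsAsFactors = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

annotation_columns <- function() {
  c("variant_key", "gene", "consequence", "gnomad_af", "gnomad_af_xy",
    "cadd_phred", paste0("tool_", tool_names()),
    "acmg_varsome", "acmg_franklin", "clinvar_hgmd")
}

#' Read the per-variant annotation sidecar table
#'
#' The sidecar is a TSV with one row per variant key carrying the external
#' evidence the pipeline consumes but never computes: gnomAD allele
#' frequencies (overall and XY/male), CADD Phred score, categorical calls
#' from the nine in-silico tools, ACMG classes from the two platforms, and a
#' ClinVar/HGMD reported flag. Empty cells become missing values, never
#' zeros.
#'
#' @param path Path to the TSV.
#' @return A data.frame keyed by `variant_key`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "ND"),
                          check.names = FALSE)
  required <- annotation_columns()
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("annotation table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  extra_tools <- setdiff(grep("^tool_", names(df), value = TRUE),
                         paste0("tool_", tool_names()))
  if (length(extra_tools)) {
    stop(sprintf("unknown tool column(s): %s",
                 paste(extra_tools, collapse = ", ")))
  }
  if (anyDuplicated(df$variant_key)) {
    stop(sprintf("duplicate variant_key in annotation table: %s",
                 df$variant_key[duplicated(df$variant_key)][1]))
  }
  for (col in c("gnomad_af", "gnomad_af_xy")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
    if (any(bad)) stop(sprintf("%s outside [0,1] for %s", col,
                               df$variant_key[bad][1]))
  }
  df$cadd_phred <- as.numeric(df$cadd_phred)
  if (any(!is.na(df$cadd_phred) & df$cadd_phred < 0)) {
    stop("cadd_phred must be non-negative")
  }
  for (col in paste0("tool_", tool_names())) {
    df[[col]] <- ifelse(is.na(df[[col]]), "missing", df[[col]])
    match_arg_vec(df[[col]], tool_call_levels(), col)
  }
  for (col in c("acmg_varsome", "acmg_franklin")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "missing", df[[col]])
    match_arg_vec(df[[col]], c(acmg_levels(), "missing"), col)
  }
  df$clinvar_hgmd <- as.logical(df$clinvar_hgmd)
  df$clinvar_hgmd[is.na(df$clinvar_hgmd)] <- FALSE
  df[required]
}

#' @rdname read_annotation_table
#' @param annotations Annotation data.frame to write.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations[annotation_columns()]
  for (col in c(paste0("tool_", tool_names()), "acmg_varsome", "acmg_franklin")) {
    out[[col]][out[[col]] == "missing"] <- NA
  }
  write_tsv(out, path)
  invisible(path)
}

#' Read the anchor-partner pair score sidecar
#'
#' Each row carries a pair-pathogenicity score (a probability in `[0,1]`
#' that the variant combination is disease-causing, as produced by a
#' VarCoPP-style predictor) and a digenic effect class for one
#' anchor-variant/partner-variant pair. `ND` or empty scores become missing,
#' mirroring combinations for which the external predictor returns no
#' prediction.
#'
#' @param path Path to the TSV with columns `anchor_key`, `partner_key`,
#'   `score`, `effect_class`.
#' @return A data.frame of pair scores.
#' @export
read_pair_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "ND"))
  required <- c("anchor_key", "partner_key", "score", "effect_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("pair score table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  df$score <- as.numeric(df$score)
  bad <- !is.na(df$score) & (df$score < 0 | df$score > 1)
  if (any(bad)) {
    stop(sprintf("pair score outside [0,1]: %s", df$score[bad][1]))
  }
  df$effect_class <- ifelse(is.na(df$effect_class), "missing", df$effect_class)
  match_arg_vec(df$effect_class, effect_class_levels(), "effect_class")
  df[required]
}

#' @rdname read_pair_scores
#' @param pair_scores Pair score data.frame to write.
#' @export
write_pair_scores <- function(pair_scores, path) {
  out <- pair_scores[c("anchor_key", "partner_key", "score", "effect_class")]
  out$effect_class[out$effect_class == "missing"] <- NA
  write_tsv(out, path)
  invisible(path)
}

#' Read a gene panel table
#'
#' @param path TSV with columns `gene` and `category` (one of `DSD`, `SF1`,
#'   `both`).
#' @return A data.frame with unique gene symbols.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(df))) {
    stop("panel table requires columns 'gene' and 'category'")
  }
  if (nrow(df) == 0L) stop("gene panel is empty")
  if (anyDuplicated(df$gene)) {
    stop(sprintf("duplicate gene in panel: %s",
                 df$gene[duplicated(df$gene)][1]))
  }
  match_arg_vec(df$category, c("DSD", "SF1", "both"), "panel category")
  df[c("gene", "category")]
}

#' Read a gene-to-pathway map
#'
#' @param path TSV with columns `gene` and `pathway_id`; a gene may appear
#'   on several rows, one per pathway.
#' @return A data.frame `gene`/`pathway_id`.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway_id") %in% names(df))) {
    stop("pathway map requires columns 'gene' and 'pathway_id'")
  }
  if (any(!nzchar(df$pathway_id))) stop("empty pathway identifier")
  df[c("gene", "pathway_id")]
}

# binary-mode TSV writer so outputs are byte-identical across platforms
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}
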