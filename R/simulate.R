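#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the structure an anchor-gene oligogenicity screen
#' assumes: each family carries one heterozygous anchor variant (inherited
#' from an asymptomatic carrier parent or arising de novo), the index case
#' carries planted partner variants inherited from the other parent or de
#' novo, background rare variants are sprinkled over the panel genes, and
#' affection status follows a digenic penetrance model — under
#' `true_digenic` a sample is affected iff it carries the anchor and at
#' least one planted partner; under `monogenic_modifier` every anchor
#' carrier is affected (mild), with severity upgraded by a partner.
#' Defaults mirror the reference cohort: 30 families, trios, mixed anchor
#' transmission. All randomness derives from the single `seed`.
#'
#' @param n_families Number of families (default 30).
#' @param pedigree_shape `"trio"`, `"quartet"` (adds a sibling) or
#'   `"extended"` (quartet plus the anchor-side grandparents).
#' @param anchor_transmission `"maternal"`, `"paternal"`, `"de_novo"` or
#'   `"mixed"` (sampled 0.4/0.4/0.2 per family).
#' @param penetrance_model `"true_digenic"` or `"monogenic_modifier"`.
#' @param n_partners Planted partner variants per index case (default 3,
#'   within the reported one-to-seven range).
#' @param partner_de_novo_rate Probability a planted partner arises de novo
#'   rather than being transmitted (default 0.1).
#' @param background_rate Mean background variants per index sample in
#'   panel genes (Poisson; default 0).
#' @param maf_range Log-uniform support of background allele frequencies
#'   (default `c(1e-6, 0.05)`, straddling the 0.01 rarity cutoff).
#' @param synonymous_fraction Fraction of background variants that are
#'   synonymous (default 0.3).
#' @param depth_mean,depth_size Negative-binomial depth model per
#'   (sample, site) (default mean 60, size 8).
#' @param min_depth,max_maf Filter conventions the planted variants are
#'   guaranteed to satisfy (defaults 20 and 0.01).
#' @param score_planted,score_background Uniform pair-score ranges for
#'   planted (default `[0.85, 1]`) and background (default `[0, 0.4575]`)
#'   pairs.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 30L,
                       pedigree_shape = c("trio", "quartet", "extended"),
                       anchor_transmission = c("mixed", "maternal",
                                               "paternal", "de_novo"),
                       penetrance_model = c("true_digenic",
                                            "monogenic_modifier"),
                       n_partners = 3L,
                       partner_de_novo_rate = 0.1,
                       background_rate = 0,
                       maf_range = c(1e-6, 0.05),
                       synonymous_fraction = 0.3,
                       depth_mean = 60, depth_size = 8,
                       min_depth = 20L, max_maf = 0.01,
                       score_planted = c(0.85, 1.0),
                       score_background = c(0, 0.4575),
                       seed = 1L) {
  pedigree_shape <- match.arg(pedigree_shape)
  anchor_transmission <- match.arg(anchor_transmission)
  penetrance_model <- match.arg(penetrance_model)
  stopifnot(n_families >= 1, n_partners >= 0,
            partner_de_novo_rate >= 0, partner_de_novo_rate <= 1,
            background_rate >= 0,
            synonymous_fraction >= 0, synonymous_fraction <= 1,
            maf_range[1] > 0, maf_range[1] < maf_range[2])
  structure(list(
    n_families = as.integer(n_families), pedigree_shape = pedigree_shape,
    anchor_transmission = anchor_transmission,
    penetrance_model = penetrance_model, n_partners = as.integer(n_partners),
    partner_de_novo_rate = partner_de_novo_rate,
    background_rate = background_rate, maf_range = maf_range,
    synonymous_fraction = synonymous_fraction,
    depth_mean = depth_mean, depth_size = depth_size,
    min_depth = as.integer(min_depth), max_maf = max_maf,
    score_planted = score_planted, score_background = score_background,
    seed = as.integer(seed)), class = "sim_config")
}

#' Synthetic gene-to-interval map
#'
#' Assigns each panel gene a deterministic 10 kb interval on synthetic
#' autosomal contigs (chr1..chr22, round-robin, layered by 500 kb). No
#' reference genome is involved; positions exist only to give variants
#' well-formed coordinates and keys.
#'
#' @param genes Character vector of gene symbols (sorted internally).
#' @return A data.frame `gene`, `chrom`, `start`, `end`.
#' @export
simulate_gene_map <- function(genes = default_panel()$gene) {
  genes <- sort(unique(genes))
  i <- seq_along(genes) - 1L
  data.frame(gene = genes,
             chrom = paste0("chr", (i %% 22L) + 1L),
             start = 1000000L + (i %/% 22L) * 500000L,
             end = 1000000L + (i %/% 22L) * 500000L + 9999L,
             stringsAsFactors = FALSE)
}

sim_bases <- c("A", "C", "G", "T")

sim_new_site <- function(gene_map, gene, used) {
  gm <- gene_map[gene_map$gene == gene, ]
  repeat {
    pos <- sample(gm$start:gm$end, 1L)
    key <- paste(gm$chrom, pos, sep = ":")
    if (!(key %in% used$sites)) {
      used$sites <- c(used$sites, key)
      return(list(chrom = gm$chrom, pos = pos))
    }
  }
}

sim_alleles <- function(consequence) {
  ref <- sample(sim_bases, 1L)
  if (consequence == "frameshift") {
    list(ref = ref, alt = paste0(ref, sample(sim_bases, 1L)))
  } else {
    list(ref = ref, alt = sample(setdiff(sim_bases, ref), 1L))
  }
}

sim_depth <- function(n, config, floor_at = NA) {
  d <- stats::rnbinom(n, size = config$depth_size, mu = config$depth_mean)
  if (!is.na(floor_at)) d <- pmax(d, floor_at)
  as.integer(d)
}

sim_tools <- function(kind) {
  switch(kind,
    pathogenic = c(rep("pathogenic_like", 7), rep("uncertain", 2)),
    benign = rep("benign_like", 9))
}

#' Simulate a synthetic cohort with planted digenic ground truth
#'
#' See [sim_config()] for the generative model. Every planted partner is
#' guaranteed to survive the filter cascade (non-synonymous, allele
#' frequency at most `max_maf`, depth at least `min_depth`) with a
#' pathogenic-leaning annotation profile, while background variants draw
#' frequencies log-uniformly across the rarity cutoff, are synonymous with
#' the configured probability, and carry benign annotations and sub-cutoff
#' pair scores.
#'
#' @param config A [sim_config()].
#' @return A list of class `oligotrio_sim`: `config`, `gene_map`,
#'   `pedigree`, `variants`, `genotypes`, `annotations`, `pair_scores`,
#'   `truth` (seed, per-family anchor/partner channels and scores, affected
#'   status per sample).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_map <- simulate_gene_map()
  partner_pool <- setdiff(gene_map$gene, default_anchor_gene())
  if (config$n_partners > length(partner_pool)) {
    stop(sprintf("n_partners (%d) exceeds available panel genes (%d)",
                 config$n_partners, length(partner_pool)))
  }
  used <- new.env(); used$sites <- character()

  ped_rows <- list(); var_rows <- list(); gt_rows <- list()
  ann_rows <- list(); pair_rows <- list(); fam_truth <- list()

  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    fa <- paste0(fam, "_fa"); mo <- paste0(fam, "_mo")
    idx <- paste0(fam, "_in")
    samples <- c(fa, mo, idx)
    sib <- NULL
    if (config$pedigree_shape %in% c("quartet", "extended")) {
      sib <- paste0(fam, "_sib"); samples <- c(samples, sib)
    }

    channel <- if (config$anchor_transmission == "mixed") {
      sample(c("maternal", "paternal", "de_novo"), 1L,
             prob = c(0.4, 0.4, 0.2))
    } else config$anchor_transmission

    gp <- character()
    if (config$pedigree_shape == "extended" && channel != "de_novo") {
      gp <- paste0(fam, c("_gf", "_gm"))
      samples <- c(samples, gp)
    }

    # anchor variant
    anchor_cons <- sample(c("missense", "frameshift", "splice_site"), 1L,
                          prob = c(0.6, 0.3, 0.1))
    site <- sim_new_site(gene_map, default_anchor_gene(), used)
    al <- sim_alleles(anchor_cons)
    anchor_key <- variant_key(site$chrom, site$pos, al$ref, al$alt)
    carrier_parent <- switch(channel, maternal = mo, paternal = fa, NULL)
    anchor_carriers <- c(idx, carrier_parent,
                         if (length(gp)) gp[1] else NULL)
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      family_id = fam, chrom = site$chrom, pos = site$pos, ref = al$ref,
      alt = al$alt, variant_key = anchor_key,
      gene_symbol = default_anchor_gene(), consequence = anchor_cons,
      type = "anchor", origin = channel, stringsAsFactors = FALSE)
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      variant_key = anchor_key, gene = default_anchor_gene(),
      consequence = anchor_cons, gnomad_af = NA_real_,
      gnomad_af_xy = NA_real_, cadd_phred = round(stats::runif(1, 25, 35), 1),
      t(stats::setNames(sim_tools("pathogenic"),
                        paste0("tool_", tool_names()))),
      acmg_varsome = "LP", acmg_franklin = "P", clinvar_hgmd = FALSE,
      stringsAsFactors = FALSE)

    # planted partners
    partner_genes <- sample(partner_pool, config$n_partners)
    partners <- list()
    other_parent <- switch(channel, maternal = fa, paternal = mo,
                           de_novo = sample(c(fa, mo), 1L))
    planted_carriers <- list()
    for (g in partner_genes) {
      site <- sim_new_site(gene_map, g, used)
      al <- sim_alleles("missense")
      key <- variant_key(site$chrom, site$pos, al$ref, al$alt)
      p_channel <- if (stats::runif(1) < config$partner_de_novo_rate) {
        "de_novo"
      } else if (other_parent == fa) "paternal" else "maternal"
      carriers <- c(idx, switch(p_channel, paternal = fa, maternal = mo,
                                NULL))
      planted_carriers[[key]] <- carriers
      af <- exp(stats::runif(1, log(config$maf_range[1]),
                             log(config$max_maf)))
      score <- stats::runif(1, config$score_planted[1],
                            config$score_planted[2])
      eff <- if (config$penetrance_model == "true_digenic")
        "true_digenic" else "monogenic_modifier"
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        family_id = fam, chrom = site$chrom, pos = site$pos, ref = al$ref,
        alt = al$alt, variant_key = key, gene_symbol = g,
        consequence = "missense", type = "planted", origin = p_channel,
        stringsAsFactors = FALSE)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        variant_key = key, gene = g, consequence = "missense",
        gnomad_af = af, gnomad_af_xy = NA_real_,
        cadd_phred = round(stats::runif(1, 20, 35), 1),
        t(stats::setNames(sim_tools("pathogenic"),
                          paste0("tool_", tool_names()))),
        acmg_varsome = "VUS", acmg_franklin = "VUS", clinvar_hgmd = FALSE,
        stringsAsFactors = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        anchor_key = anchor_key, partner_key = key, score = score,
        effect_class = eff, stringsAsFactors = FALSE)
      partners[[length(partners) + 1L]] <- data.frame(
        partner_key = key, gene = g, channel = p_channel, score = score,
        effect_class = eff, stringsAsFactors = FALSE)
    }
    partners <- if (length(partners)) do.call(rbind, partners) else
      data.frame(partner_key = character(), gene = character(),
                 channel = character(), score = numeric(),
                 effect_class = character(), stringsAsFactors = FALSE)

    # background variants observed in the index
    bg_carriers <- list(); bg_keys <- character()
    n_bg <- stats::rpois(1, config$background_rate)
    for (b in seq_len(n_bg)) {
      g <- sample(partner_pool, 1L)
      site <- sim_new_site(gene_map, g, used)
      cons <- if (stats::runif(1) < config$synonymous_fraction)
        "synonymous" else "missense"
      al <- sim_alleles(cons)
      key <- variant_key(site$chrom, site$pos, al$ref, al$alt)
      origin <- sample(c("paternal", "maternal", "de_novo"), 1L,
                       prob = c(0.45, 0.45, 0.1))
      carriers <- c(idx, switch(origin, paternal = fa, maternal = mo, NULL))
      bg_carriers[[key]] <- carriers
      bg_keys <- c(bg_keys, key)
      af <- exp(stats::runif(1, log(config$maf_range[1]),
                             log(config$maf_range[2])))
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        family_id = fam, chrom = site$chrom, pos = site$pos, ref = al$ref,
        alt = al$alt, variant_key = key, gene_symbol = g,
        consequence = cons, type = "background", origin = origin,
        stringsAsFactors = FALSE)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        variant_key = key, gene = g, consequence = cons, gnomad_af = af,
        gnomad_af_xy = NA_real_,
        cadd_phred = round(stats::runif(1, 0, 14), 1),
        t(stats::setNames(sim_tools("benign"),
                          paste0("tool_", tool_names()))),
        acmg_varsome = "B", acmg_franklin = "LB", clinvar_hgmd = FALSE,
        stringsAsFactors = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        anchor_key = anchor_key, partner_key = key,
        score = stats::runif(1, config$score_background[1],
                             config$score_background[2]),
        effect_class = "missing", stringsAsFactors = FALSE)
    }

    # sibling genotypes: independent 50% transmission from each carrier
    carriers_of <- c(list(), stats::setNames(list(anchor_carriers),
                                             anchor_key),
                     planted_carriers, bg_carriers)
    if (!is.null(sib)) {
      for (key in names(carriers_of)) {
        carrier_parents <- intersect(carriers_of[[key]], c(fa, mo))
        transmitted <- carrier_parents[stats::runif(
          length(carrier_parents)) < 0.5]
        if (length(transmitted)) {
          carriers_of[[key]] <- c(carriers_of[[key]], sib)
        }
      }
    }

    # genotype rows with simulated depth; planted/anchor sites floored
    for (key in names(carriers_of)) {
      is_planted <- key %in% c(anchor_key, partners$partner_key)
      depth <- sim_depth(length(samples), config,
                         floor_at = if (is_planted) config$min_depth else NA)
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        family_id = fam, sample_id = samples, variant_key = key,
        zygosity = ifelse(samples %in% carriers_of[[key]], "het",
                          "hom_ref"),
        depth = depth, stringsAsFactors = FALSE)
    }

    # affection by penetrance model
    has_anchor <- samples %in% carriers_of[[anchor_key]]
    has_partner <- rep(FALSE, length(samples))
    for (key in partners$partner_key) {
      has_partner <- has_partner | samples %in% carriers_of[[key]]
    }
    affected <- if (config$penetrance_model == "true_digenic") {
      has_anchor & has_partner
    } else {
      has_anchor
    }
    affection <- rep("asymptomatic", length(samples))
    if (config$penetrance_model == "true_digenic") {
      affection[affected] <- "severe_DSD"
    } else {
      affection[affected] <- ifelse(has_partner[affected], "severe_DSD",
                                    "mild_DSD")
    }

    father_id <- ifelse(samples %in% c(idx, sib), fa, "")
    mother_id <- ifelse(samples %in% c(idx, sib), mo, "")
    if (length(gp)) {  # grandparents on the anchor-carrier side
      father_id[samples == carrier_parent] <- gp[1]
      mother_id[samples == carrier_parent] <- gp[2]
    }
    male <- c(fa, idx, sib, if (length(gp)) gp[1])
    ped_rows[[length(ped_rows) + 1L]] <- data.frame(
      sample_id = samples, family_id = fam,
      father_id = father_id, mother_id = mother_id,
      karyotype = ifelse(samples %in% male, "46,XY", "46,XX"),
      affection = affection,
      phenotype_notes = "", is_index = samples == idx,
      stringsAsFactors = FALSE)

    fam_truth[[fam]] <- list(
      index_id = idx, anchor_key = anchor_key, anchor_channel = channel,
      partners = partners, background_keys = bg_keys,
      affected = stats::setNames(as.list(affected), samples))
  }

  pedigree <- do.call(rbind, ped_rows); rownames(pedigree) <- NULL
  variants <- do.call(rbind, var_rows); rownames(variants) <- NULL
  genotypes <- do.call(rbind, gt_rows); rownames(genotypes) <- NULL
  annotations <- do.call(rbind, ann_rows); rownames(annotations) <- NULL
  pair_scores <- do.call(rbind, pair_rows); rownames(pair_scores) <- NULL

  structure(list(config = config, gene_map = gene_map, pedigree = pedigree,
                 variants = variants, genotypes = genotypes,
                 annotations = annotations, pair_scores = pair_scores,
                 truth = list(seed = config$seed,
                              penetrance_model = config$penetrance_model,
                              families = fam_truth)),
            class = "oligotrio_sim")
}

zygosity_to_gt <- function(zygosity) {
  switch(zygosity, hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
         hemizygous = "1/1", missing = "./.")
}

chrom_order <- function(chrom) {
  as.integer(sub("^chr", "", chrom))
}

write_family_vcf <- function(sim, fam, path) {
  v <- sim$variants[sim$variants$family_id == fam, , drop = FALSE]
  v <- v[order(chrom_order(v$chrom), v$pos), , drop = FALSE]
  g <- sim$genotypes[sim$genotypes$family_id == fam, , drop = FALSE]
  samples <- unique(sim$pedigree$sample_id[sim$pedigree$family_id == fam])
  contigs <- unique(v$chrom[order(chrom_order(v$chrom))])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oligotrio_synthetic",
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    gi <- g[g$variant_key == v$variant_key[i], , drop = FALSE]
    cells <- vapply(samples, function(s) {
      r <- gi[gi$sample_id == s, , drop = FALSE]
      if (nrow(r) == 0L) return("./.:.")
      paste0(zygosity_to_gt(r$zygosity[1]), ":", r$depth[1])
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            paste0("GENE=", v$gene_symbol[i], ";CSQ=", v$consequence[i]),
            "GT:DP", cells), collapse = "\t")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF v4.2 per family plus cohort-wide PED, annotation sidecar,
#' pair-score sidecar and ground-truth JSON, all cross-consistent (every
#' VCF alternate allele has exactly one sidecar row). Files contain no
#' timestamps, so a fixed seed reproduces them byte-identically.
#'
#' @param sim An `oligotrio_sim` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return A list of paths: `vcf` (named by family), `ped`, `annotations`,
#'   `pair_scores`, `truth`.
#' @export
emit_files <- function(sim, out_dir) {
  stopifnot(inherits(sim, "oligotrio_sim"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  fams <- unique(sim$pedigree$family_id)
  vcf_paths <- stats::setNames(
    file.path(out_dir, paste0("fam_", fams, ".vcf")), fams)
  for (fam in fams) write_family_vcf(sim, fam, vcf_paths[[fam]])
  ped_path <- file.path(out_dir, "cohort.ped")
  write_ped(sim$pedigree, ped_path)
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_annotation_table(sim$annotations, ann_path)
  ps_path <- file.path(out_dir, "pair_scores.tsv")
  write_pair_scores(sim$pair_scores, ps_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(vcf = vcf_paths, ped = ped_path, annotations = ann_path,
       pair_scores = ps_path, truth = truth_path)
}

#' Compare pipeline output against planted ground truth
#'
#' Pair-level precision and recall plus inheritance-call accuracy. A
#' planted pair counts as recoverable when its assigned score reaches the
#' confidence-zone cutoff (it was constructed to pass the filter cascade).
#' Precision is computed over all retained pairs, recall over recoverable
#' planted pairs. The run manifest's seed must match the truth's seed.
#'
#' @param result A pipeline result list from [run_all()] (needs
#'   `case_results`, `inheritance`, `manifest`).
#' @param truth The `truth` element of an `oligotrio_sim` (or re-read from
#'   `truth.json`).
#' @param thresholds A [pair_thresholds()].
#' @return A list: `precision`, `recall`, `inheritance_accuracy`,
#'   `n_retained`, `n_planted`, `n_recoverable`.
#' @export
truth_compare <- function(result, truth, thresholds = pair_thresholds()) {
  if (!identical(as.integer(result$manifest$seed),
                 as.integer(truth$seed))) {
    stop(sprintf("manifest seed (%s) does not match truth seed (%s)",
                 result$manifest$seed, truth$seed))
  }
  planted <- do.call(rbind, lapply(names(truth$families), function(fam) {
    ft <- truth$families[[fam]]
    p <- ft$partners
    if (is.null(p) || NROW(p) == 0L) return(NULL)
    data.frame(case_id = ft$index_id, partner_key = p$partner_key,
               score = p$score, channel = p$channel,
               stringsAsFactors = FALSE)
  }))
  planted_ids <- if (is.null(planted)) character() else
    paste(planted$case_id, planted$partner_key)
  recoverable <- if (is.null(planted)) character() else
    planted_ids[planted$score >= thresholds$confidence_zone]
  cr <- result$case_results
  retained_ids <- paste(cr$case_id, cr$variant_key)[cr$retained]
  tp <- length(intersect(retained_ids, planted_ids))
  precision <- if (length(retained_ids)) tp / length(retained_ids) else NA_real_
  recall <- if (length(recoverable))
    length(intersect(retained_ids, recoverable)) / length(recoverable) else
      NA_real_
  inh_acc <- NA_real_
  if (!is.null(result$inheritance) && !is.null(planted)) {
    inh <- result$inheritance
    ids <- paste(inh$sample_id, inh$variant_key)
    m <- match(paste(planted$case_id, planted$partner_key), ids)
    ok <- !is.na(m)
    if (any(ok)) {
      inh_acc <- mean(inh$call[m[ok]] == planted$channel[ok])
    }
  }
  list(precision = precision, recall = recall,
       inheritance_accuracy = inh_acc, n_retained = length(retained_ids),
       n_planted = length(planted_ids), n_recoverable = length(recoverable))
}
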