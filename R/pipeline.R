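`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse the human-editable pipeline configuration file
#'
#' The file is plain `key: value` lines with dotted section keys, e.g.
#' `filter.min_depth: 20` or `sim.n_families: 30`; blank lines and lines
#' starting with `#` are ignored. Values are parsed as numbers or logicals
#' when they look like one. All schema violations are collected and
#' reported in a single aggregated error before any computation.
#'
#' @param path Path to the config file.
#' @return A nested list (`mode`, `out_dir`, `seed`, and the `filter`,
#'   `thresholds`, `consensus`, `sim` sections).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  errors <- character()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      errors <- c(errors, sprintf("not a key: value line: '%s'", ln))
      next
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (grepl("^-?[0-9.eE+-]+$", val) &&
        !is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    } else if (val %in% c("true", "false", "TRUE", "FALSE")) {
      val <- tolower(val) == "true"
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) cfg[[parts]] <- val
    else cfg[[parts[1]]][[parts[2]]] <- val
  }
  known_sections <- c("filter", "thresholds", "consensus", "sim")
  known_top <- c("mode", "out_dir", "seed", known_sections)
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$mode) && !(cfg$mode %in% c("fixture", "simulate"))) {
    errors <- c(errors, sprintf("mode must be 'fixture' or 'simulate', got '%s'",
                                cfg$mode))
  }
  if (!is.null(cfg$filter$panel_path) && !file.exists(cfg$filter$panel_path)) {
    errors <- c(errors, sprintf("filter.panel_path does not exist: %s",
                                cfg$filter$panel_path))
  }
  if (length(errors)) {
    stop(paste(c("invalid pipeline configuration:", errors),
               collapse = "\n  "))
  }
  cfg
}

manifest_new <- function(config, seed, input_paths = character()) {
  hashes <- if (length(input_paths)) {
    as.list(tools::md5sum(unlist(input_paths)))
  } else list()
  list(tool = "oligotrio",
       version = as.character(utils::packageVersion("oligotrio")),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config, input_hashes = hashes,
       stage_counts = list(), failed_families = character())
}

#' Run the full pipeline end to end
#'
#' Executes the stages in fixed order — io, filter cascade, consensus, pair
#' building and selection, segregation, cohort summary — under a single
#' configuration list, and writes TSV/JSON reports plus a run manifest to
#' `out_dir`. In `simulate` mode a synthetic cohort is generated, written
#' to disk, and read back through the regular file readers so the whole io
#' surface is exercised; in `fixture` mode the packaged cohort tables are
#' analysed (these are post-filter candidate rows, so the cascade stage is
#' a pass-through there). Failure of one family does not abort the cohort:
#' the family is recorded under `failed_families` in the manifest.
#'
#' @param config A nested configuration list as returned by
#'   [read_pipeline_config()], or built directly; recognised keys:
#'   `mode` (`"fixture"`/`"simulate"`), `out_dir`, `seed`, and the
#'   `filter`, `thresholds`, `sim` sections.
#' @return A list: `case_results`, `filter_decisions` (simulate mode),
#'   `inheritance`, `cosegregation`, `summary`, `manifest`, `files`.
#' @export
run_all <- function(config) {
  mode <- config$mode %||% "fixture"
  if (!mode %in% c("fixture", "simulate")) {
    stop("config$mode must be 'fixture' or 'simulate'")
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  thresholds <- do.call(pair_thresholds, config$thresholds %||% list())
  if (mode == "fixture") {
    run_all_fixture(config, out_dir, thresholds)
  } else {
    run_all_simulate(config, out_dir, thresholds)
  }
}

run_all_fixture <- function(config, out_dir, thresholds) {
  fixture <- load_fixture_cohort()
  case_results <- run_fixture_pipeline(fixture, thresholds)
  summary <- cohort_summary(case_results, case_ids = fixture$cases$case_id)
  manifest <- manifest_new(config, seed = config$seed %||% NA_integer_)
  manifest$stage_counts <- list(
    cases = nrow(fixture$cases), variants = nrow(fixture$variants),
    retained = sum(case_results$retained),
    rejected = sum(!case_results$retained))
  files <- write_reports(case_results, summary, manifest, out_dir)
  list(case_results = case_results, filter_decisions = NULL,
       inheritance = NULL, cosegregation = NULL, summary = summary,
       manifest = manifest, files = files)
}

run_all_simulate <- function(config, out_dir, thresholds) {
  sim_args <- config$sim %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  sim_cfg <- do.call(sim_config, sim_args)
  sim <- simulate_cohort(sim_cfg)
  input_dir <- file.path(out_dir, "input")
  paths <- emit_files(sim, input_dir)

  pedigree <- read_ped(paths$ped)
  annotations <- read_annotation_table(paths$annotations)
  pair_scores <- read_pair_scores(paths$pair_scores)
  filter_args <- config$filter %||% list()
  filter_args$min_depth <- filter_args$min_depth %||% sim_cfg$min_depth
  filter_args$max_maf <- filter_args$max_maf %||% sim_cfg$max_maf
  fc <- do.call(filter_config, filter_args)
  consensus <- criterion2_eval(annotations)
  gene_of <- stats::setNames(annotations$gene, annotations$variant_key)

  manifest <- manifest_new(config, seed = sim_cfg$seed,
                           input_paths = c(paths$ped, paths$annotations,
                                           paths$pair_scores,
                                           unname(paths$vcf)))
  fams <- unique(pedigree$family_id)
  all_results <- list(); all_filter <- list(); all_inh <- list()
  all_coseg <- list(); index_ids <- character()

  for (fam in fams) {
    res <- tryCatch({
      fam_ped <- pedigree[pedigree$family_id == fam, , drop = FALSE]
      vcf <- read_vcf(paths$vcf[[fam]], fam_ped)
      fd <- run_cascade(vcf$variants, vcf$genotypes, annotations, fam_ped,
                        fc)
      idx <- fam_ped$sample_id[fam_ped$is_index][1]
      retained_keys <- fd$variant_key[fd$retained]
      anchor_keys <- retained_keys[
        vcf$variants$gene_symbol[match(retained_keys,
                                       vcf$variants$variant_key)] ==
          fc$anchor_gene]
      anchor_key <- if (length(anchor_keys)) anchor_keys[1] else NA
      anchor_scorable <- !is.na(anchor_key) &&
        vcf$variants$scorable[vcf$variants$variant_key == anchor_key]
      candidates <- setdiff(retained_keys, anchor_key)
      pairs <- build_pairs(anchor_key %||% "", candidates, pair_scores,
                           anchor_scorable = isTRUE(anchor_scorable))
      dec <- select_candidates(pairs, consensus, gene_of = gene_of,
                               thresholds = thresholds)
      inh <- NULL; coseg <- NULL
      keys_to_call <- unique(c(if (!is.na(anchor_key)) anchor_key,
                               dec$partner_key[dec$retained]))
      if (length(keys_to_call)) {
        inh <- do.call(rbind, lapply(keys_to_call, call_inheritance,
                                     index_id = idx, pedigree = fam_ped,
                                     genotypes = vcf$genotypes,
                                     min_depth = fc$min_depth))
      }
      ret_partners <- dec$partner_key[dec$retained]
      if (length(ret_partners) && !is.na(anchor_key)) {
        coseg <- do.call(rbind, lapply(ret_partners, function(pk) {
          cs <- cosegregation_consistency(anchor_key, pk, fam_ped,
                                          vcf$genotypes, idx)
          data.frame(family_id = fam, anchor_key = anchor_key,
                     partner_key = pk, n_evaluable = cs$n_evaluable,
                     n_consistent = cs$n_consistent,
                     consistency = cs$consistency,
                     counterexamples = paste(cs$counterexamples,
                                             collapse = ","),
                     stringsAsFactors = FALSE)
        }))
      }
      cr <- if (nrow(dec)) data.frame(
        case_id = idx, family_id = fam,
        gene_symbol = unname(gene_of[dec$partner_key]),
        variant_key = dec$partner_key, score = dec$score,
        effect_class = dec$effect_class,
        disease_causing = dec$disease_causing,
        in_confidence_zone = dec$in_confidence_zone,
        criterion1 = dec$criterion1, criterion2 = dec$criterion2,
        phenotype_rejected = dec$phenotype_rejected,
        retained = dec$retained, rationale = dec$rationale,
        cadd_phred = annotations$cadd_phred[
          match(dec$partner_key, annotations$variant_key)],
        case_flag = "", stringsAsFactors = FALSE) else NULL
      list(cr = cr, fd = fd, inh = inh, coseg = coseg, idx = idx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_families <- c(manifest$failed_families, fam)
      warning(sprintf("family %s failed: %s", fam, conditionMessage(res)))
      next
    }
    index_ids <- c(index_ids, res$idx)
    all_results[[fam]] <- res$cr
    all_filter[[fam]] <- res$fd
    all_inh[[fam]] <- res$inh
    all_coseg[[fam]] <- res$coseg
  }

  case_results <- do.call(rbind, all_results)
  if (is.null(case_results)) {
    case_results <- data.frame(case_id = character(),
                               family_id = character(),
                               gene_symbol = character(),
                               variant_key = character(), score = numeric(),
                               effect_class = character(),
                               retained = logical(),
                               cadd_phred = numeric(),
                               stringsAsFactors = FALSE)
  }
  filter_decisions <- do.call(rbind, all_filter)
  inheritance <- do.call(rbind, all_inh)
  cosegregation <- do.call(rbind, all_coseg)
  rownames(case_results) <- NULL

  summary <- cohort_summary(case_results, case_ids = index_ids)
  manifest$stage_counts <- list(
    families = length(fams),
    variants_input = if (is.null(filter_decisions)) 0L else
      nrow(filter_decisions),
    variants_retained = if (is.null(filter_decisions)) 0L else
      sum(filter_decisions$retained),
    variants_rejected = if (is.null(filter_decisions)) 0L else
      sum(!filter_decisions$retained),
    pairs_built = nrow(case_results),
    pairs_retained = sum(case_results$retained))
  files <- write_reports(case_results, summary, manifest, out_dir,
                         filter_decisions = filter_decisions,
                         inheritance = inheritance,
                         cosegregation = cosegregation)
  list(case_results = case_results, filter_decisions = filter_decisions,
       inheritance = inheritance, cosegregation = cosegregation,
       summary = summary, manifest = manifest, files = c(paths, files),
       sim = sim)
}

summary_for_json <- function(summary) {
  s <- summary
  s$mean_cadd <- if (is.na(s$mean_cadd)) NULL else s$mean_cadd
  s
}

write_reports <- function(case_results, summary, manifest, out_dir,
                          filter_decisions = NULL, inheritance = NULL,
                          cosegregation = NULL) {
  files <- list()
  files$case_results <- file.path(out_dir, "case_results.tsv")
  write_tsv(case_results, files$case_results)
  files$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_for_json(summary), files$summary,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(filter_decisions)) {
    files$filter_decisions <- file.path(out_dir, "filter_decisions.tsv")
    write_tsv(filter_decisions, files$filter_decisions)
  }
  if (!is.null(inheritance)) {
    files$inheritance <- file.path(out_dir, "inheritance.tsv")
    write_tsv(inheritance, files$inheritance)
  }
  if (!is.null(cosegregation)) {
    files$cosegregation <- file.path(out_dir, "cosegregation.tsv")
    write_tsv(cosegregation, files$cosegregation)
  }
  files
}

#' Render per-case reports
#'
#' Writes the case-results table in the requested format(s) together with a
#' per-case narrative text block listing each case's retained candidates,
#' deciding criteria and (when available) inheritance calls — the style of
#' a worked family-analysis summary.
#'
#' @param result A pipeline result list from [run_all()].
#' @param out_dir Output directory.
#' @param format `"tsv"`, `"json"` or `"both"`.
#' @return Invisibly, the list of written paths.
#' @export
report <- function(result, out_dir, format = c("both", "tsv", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop(sprintf(
                       "unknown report format '%s'", format[1])))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cr <- result$case_results
  files <- list()
  if (format %in% c("tsv", "both")) {
    files$tsv <- file.path(out_dir, "report_cases.tsv")
    write_tsv(cr, files$tsv)
  }
  if (format %in% c("json", "both")) {
    files$json <- file.path(out_dir, "report_cases.json")
    jsonlite::write_json(cr, files$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  narrative <- unlist(lapply(split(cr, cr$case_id), function(d) {
    ret <- d[d$retained, , drop = FALSE]
    flag <- unique(d$case_flag[nzchar(d$case_flag)])
    head <- sprintf("Case %s: %d candidate variant(s), %d retained%s",
                    d$case_id[1], nrow(d), nrow(ret),
                    if (length(flag)) paste0(" [", flag, "]") else "")
    lines <- if (nrow(ret)) {
      inh <- result$inheritance
      vapply(seq_len(nrow(ret)), function(i) {
        call <- if (!is.null(inh)) {
          m <- inh$call[inh$variant_key == ret$variant_key[i] &
                          inh$sample_id == ret$case_id[i]]
          if (length(m)) paste0("; inheritance: ", m[1]) else ""
        } else ""
        sprintf("  - %s (%s): %s%s", ret$variant_key[i],
                ret$gene_symbol[i], ret$rationale[i], call)
      }, character(1))
    } else character()
    c(head, lines)
  }), use.names = FALSE)
  files$narrative <- file.path(out_dir, "report_narrative.txt")
  con <- file(files$narrative, "wb")
  writeLines(narrative, con)
  close(con)
  invisible(files)
}
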