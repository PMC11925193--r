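#' @keywords internal
"_PACKAGE"

#' Controlled vocabularies of the data model
#'
#' Constant accessors for the vocabularies shared by all pipeline stages:
#' the nine in-silico prediction tools whose calls are aggregated into the
#' per-variant consensus, the ACMG class ordering, variant consequence
#' classes, zygosity states, digenic effect classes and affection classes.
#'
#' @return A character vector of the vocabulary.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
tool_names <- function() {
  c("polyphen2", "panther", "snpsgo", "cadd", "sift",
    "provean", "revel", "mutationtaster", "mcap")
}

#' @rdname vocabularies
#' @export
tool_call_levels <- function() {
  c("pathogenic_like", "benign_like", "uncertain", "missing")
}

#' @rdname vocabularies
#' @export
acmg_levels <- function() {
  # ordered benign -> pathogenic; "missing" sorts below everything
  c("B", "LB", "VUS", "LP", "P")
}

#' @rdname vocabularies
#' @export
consequence_levels <- function() {
  c("synonymous", "missense", "frameshift", "inframe_indel", "splice_site",
    "stop_gained", "start_lost", "duplication", "structural_deletion", "other")
}

#' @rdname vocabularies
#' @export
zygosity_levels <- function() {
  c("hom_ref", "het", "hom_alt", "hemizygous", "missing")
}

#' @rdname vocabularies
#' @export
effect_class_levels <- function() {
  c("true_digenic", "monogenic_modifier", "dual_diagnosis", "missing")
}

#' @rdname vocabularies
#' @export
affection_levels <- function() {
  c("asymptomatic", "mild_DSD", "severe_DSD", "opposite_sex_DSD", "POI",
    "other_affected", "unknown")
}

#' Default anchor gene symbol
#'
#' The anchor gene against which every candidate variant is paired. The
#' default, `NR5A1` (steroidogenic factor 1, SF-1), is the gene whose
#' heterozygous variants define entry into an SF-1 related DSD cohort; any
#' other anchor symbol may be passed to the functions that take one.
#'
#' @return A single gene symbol string.
#' @export
default_anchor_gene <- function() "NR5A1"

is_symbolic_allele <- function(alt) {
  grepl("^<.*>$", alt) | grepl("[][]", alt)
}

#' Normalize variant alleles and build canonical variant keys
#'
#' Trims bases shared between REF and ALT so that equivalent spellings of the
#' same allele collapse to one canonical identity. Shared trailing bases are
#' removed first, then shared leading bases (advancing `pos`), always leaving
#' at least one base in each allele. Symbolic alleles (`<DEL>`, `<DUP>`, and
#' breakend notation) are passed through untouched and flagged non-scorable
#' downstream. Normalization is idempotent and the resulting
#' `variant_key` (`"chrom:pos:ref:alt"`) is invariant to padding with shared
#' context bases.
#'
#' @param chrom Contig names (character).
#' @param pos 1-based positions (integer).
#' @param ref,alt Allele strings (uppercased on entry).
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_key`.
#' @examples
#' normalize_variant("1", 100, "CAG", "CAA")  # -> 1:102:G:A
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(alt),
            length(pos) == length(ref))
  ref <- toupper(ref)
  alt <- ifelse(is_symbolic_allele(alt), alt, toupper(alt))
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("variant position must be >= 1")
  if (any(!is_symbolic_allele(alt) & ref == alt)) {
    stop("REF and ALT must differ")
  }
  n <- length(pos)
  for (i in seq_len(n)) {
    if (is_symbolic_allele(alt[i])) next
    r <- ref[i]; a <- alt[i]
    # trim shared trailing bases
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared leading bases, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             variant_key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

#' @rdname normalize_variant
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  normalize_variant(chrom, pos, ref, alt)$variant_key
}

sex_chromosomes <- function() c("X", "Y", "chrX", "chrY")

is_sex_chrom <- function(chrom) chrom %in% sex_chromosomes()

#' Map a VCF genotype call to a zygosity state
#'
#' Converts allele dosages into the zygosity vocabulary, taking the sample's
#' karyotype into account on the sex chromosomes: for a 46,XY sample a
#' single-copy or homozygous alternate call on chrX/chrY becomes
#' `hemizygous`, while a heterozygous chrX call is retained as `het` but
#' flagged `pseudo-autosomal-or-artifact`. A depth of zero forces `missing`.
#'
#' @param dosage Count of the alternate allele in the call (0, 1, 2) or `NA`
#'   for an uncalled genotype.
#' @param ploidy Number of alleles in the call (1 or 2).
#' @param chrom Contig of the variant.
#' @param karyotype Sample karyotype string (`"46,XY"`, `"46,XX"`, `"other"`).
#' @param depth Read depth at the site (`NA` if unknown).
#' @return A data.frame with columns `zygosity` and `flag` (empty string when
#'   no flag applies).
#' @export
genotype_to_zygosity <- function(dosage, ploidy, chrom, karyotype, depth) {
  n <- length(dosage)
  zyg <- character(n)
  flag <- character(n)
  male <- karyotype == "46,XY"
  sexc <- is_sex_chrom(chrom)
  for (i in seq_len(n)) {
    if (is.na(dosage[i]) || (!is.na(depth[i]) && depth[i] == 0L)) {
      zyg[i] <- "missing"; flag[i] <- ""
      next
    }
    d <- dosage[i]
    if (male[i] && sexc[i]) {
      if (ploidy[i] == 1L) {
        zyg[i] <- if (d >= 1L) "hemizygous" else "hom_ref"
      } else if (d == 2L) {
        zyg[i] <- "hemizygous"
      } else if (d == 1L) {
        zyg[i] <- "het"
        flag[i] <- "pseudo-autosomal-or-artifact"
      } else {
        zyg[i] <- "hom_ref"
      }
    } else {
      zyg[i] <- switch(as.character(d), "0" = "hom_ref", "1" = "het",
                       "2" = "hom_alt", "hom_alt")
    }
    if (is.na(flag[i])) flag[i] <- ""
  }
  data.frame(zygosity = zyg, flag = flag, stringsAsFactors = FALSE)
}

match_arg_vec <- function(x, choices, what, allow_na = FALSE) {
  bad <- !(x %in% choices) & !(allow_na & is.na(x))
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")))
  }
  x
}
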