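test_that("allele normalization trims shared context and is idempotent", {
  # worked example: CAG>CAA at 100 shares C.A prefix/suffix -> G>A at 102
  n <- normalize_variant("1", 100, "CAG", "CAA")
  expect_equal(n$pos, 102L)
  expect_equal(n$ref, "G")
  expect_equal(n$alt, "A")
  expect_equal(n$variant_key, "1:102:G:A")
  # key equals that of the pre-trimmed equivalent
  expect_equal(n$variant_key, variant_key("1", 102, "G", "A"))

  # property: padding a minimal variant with shared bases never changes its
  # key. Minimal here means the allele edges differ (equal-length variants);
  # indel representations in repeat context are not position-canonical
  # without a reference sequence and are excluded from this property.
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  rand_pair <- function() {
    len <- sample(1:3, 1)
    repeat {
      ref <- paste(sample(bases, len, replace = TRUE), collapse = "")
      alt <- paste(sample(bases, len, replace = TRUE), collapse = "")
      first_differ <- substr(ref, 1, 1) != substr(alt, 1, 1)
      last_differ <- substr(ref, len, len) != substr(alt, len, len)
      if (first_differ && last_differ) return(c(ref, alt))
    }
  }
  for (i in 1:50) {
    pair <- rand_pair(); ref <- pair[1]; alt <- pair[2]
    pos <- sample(10:1000, 1)
    base_key <- variant_key("7", pos, ref, alt)
    prefix <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                    collapse = "")
    suffix <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                    collapse = "")
    padded <- normalize_variant("7", pos - nchar(prefix),
                                paste0(prefix, ref, suffix),
                                paste0(prefix, alt, suffix))
    expect_equal(padded$variant_key, base_key)
    # idempotence
    again <- normalize_variant(padded$chrom, padded$pos, padded$ref,
                               padded$alt)
    expect_equal(again$variant_key, padded$variant_key)
  }
})

test_that("normalization rejects invalid alleles and keeps symbolic ones", {
  expect_error(normalize_variant("1", 0, "A", "C"), "position")
  expect_error(normalize_variant("1", 5, "A", "A"), "differ")
  n <- normalize_variant("9", 100, "N", "<DEL>")
  expect_equal(n$alt, "<DEL>")
})

test_that("read_vcf maps genotypes, depth and karyotype-aware zygosity", {
  ped <- mk_trio_ped()
  path <- write_test_vcf(c(
    vcf_row("chr1", 100, "A", "G", "GENE=GLI3;CSQ=missense", "GT:DP",
            "0/0:40", "0/1:28", "0/1:35"),
    vcf_row("chrX", 500, "T", "C", "GENE=AR;CSQ=missense", "GT:DP",
            "1/1:30", "0/1:30", "0/1:22")))
  x <- read_vcf(path, ped)
  expect_equal(nrow(x$variants), 2L)
  g1 <- x$genotypes[x$genotypes$variant_key == "chr1:100:A:G", ]
  expect_equal(g1$zygosity[g1$sample_id == "idx"], "het")
  expect_equal(g1$depth[g1$sample_id == "idx"], 35L)
  expect_equal(g1$zygosity[g1$sample_id == "fa"], "hom_ref")
  # 46,XY on chrX: 1/1 -> hemizygous; 0/1 -> het but flagged
  gx <- x$genotypes[x$genotypes$variant_key == "chrX:500:T:C", ]
  expect_equal(gx$zygosity[gx$sample_id == "fa"], "hemizygous")
  expect_equal(gx$zygosity[gx$sample_id == "idx"], "het")
  expect_equal(gx$flag[gx$sample_id == "idx"], "pseudo-autosomal-or-artifact")
  # 46,XX mother: plain het
  expect_equal(gx$zygosity[gx$sample_id == "mo"], "het")
  expect_equal(gx$flag[gx$sample_id == "mo"], "")
})

test_that("multiallelic records decompose and conserve allele counts", {
  ped <- mk_trio_ped()
  path <- write_test_vcf(c(
    vcf_row("chr1", 200, "C", "A,T", "CSQ=missense", "GT:DP",
            "1/2:30", "0/1:30", "2/2:30")))
  x <- read_vcf(path, ped)
  expect_equal(nrow(x$variants), 2L)
  expect_setequal(x$variants$variant_key, c("chr1:200:C:A", "chr1:200:C:T"))
  # per-sample alt dosages sum to the original call's alt-allele count
  for (s in c("fa", "mo", "idx")) {
    g <- x$genotypes[x$genotypes$sample_id == s, ]
    expected <- c(fa = 2L, mo = 1L, idx = 2L)[[s]]
    expect_equal(sum(g$dosage), expected)
  }
  # 1/2 decomposes to het on both alleles; 2/2 to hom_alt on alt 2 only
  g <- x$genotypes
  expect_equal(g$zygosity[g$sample_id == "fa" &
                            g$variant_key == "chr1:200:C:A"], "het")
  expect_equal(g$zygosity[g$sample_id == "idx" &
                            g$variant_key == "chr1:200:C:T"], "hom_alt")
  expect_equal(g$zygosity[g$sample_id == "idx" &
                            g$variant_key == "chr1:200:C:A"], "hom_ref")
})

test_that("read_vcf depth precedence is FORMAT DP, then AD sum, then INFO DP", {
  ped <- mk_trio_ped()
  path <- write_test_vcf(c(
    vcf_row("chr1", 10, "A", "G", "DP=99", "GT:AD", "0/1:12,13", "0/0:5,0",
            "0/1:20,21"),
    vcf_row("chr1", 20, "A", "G", "DP=77", "GT", "0/1", "0/0", "0/1")))
  x <- read_vcf(path, ped)
  g1 <- x$genotypes[x$genotypes$variant_key == "chr1:10:A:G", ]
  expect_equal(g1$depth[g1$sample_id == "idx"], 41L)  # AD sum
  g2 <- x$genotypes[x$genotypes$variant_key == "chr1:20:A:G", ]
  expect_equal(g2$depth[g2$sample_id == "idx"], 77L)  # INFO DP fallback
})

test_that("read_vcf errors name unknown samples and zero depth is missing", {
  ped <- mk_trio_ped()
  path <- write_test_vcf(
    vcf_row("chr1", 10, "A", "G", ".", "GT:DP", "0/1:30", "0/1:30",
            "0/1:30"),
    samples = c("fa", "mo", "stranger"))
  expect_error(read_vcf(path, ped), "stranger")

  path2 <- write_test_vcf(c(
    vcf_row("chr1", 10, "A", "G", ".", "GT:DP", "0/1:0", "./.:30",
            "0/1:30")))
  x <- read_vcf(path2, ped)
  g <- x$genotypes
  expect_equal(g$zygosity[g$sample_id == "fa"], "missing")  # depth 0
  expect_equal(g$zygosity[g$sample_id == "mo"], "missing")  # uncalled
})

test_that("read_ped builds families, flags orphans, rejects bad structure", {
  path <- tempfile()
  writeLines(c(
    "#family_id sample_id father_id mother_id sex phenotype karyotype affection is_index",
    "F1 fa 0 0 1 1 46,XY asymptomatic 0",
    "F1 mo 0 0 2 1 46,XX asymptomatic 0",
    "F1 idx fa mo 1 2 46,XY severe_DSD 1",
    "F2 solo 0 0 2 2 46,XY opposite_sex_DSD 1"), path)
  ped <- read_ped(path)
  expect_equal(nrow(ped), 4L)
  expect_equal(sort(unique(ped$family_id)), c("F1", "F2"))
  expect_equal(ped$father_id[ped$sample_id == "idx"], "fa")
  expect_true(ped$is_index[ped$sample_id == "idx"])
  expect_equal(ped$affection[ped$sample_id == "solo"], "opposite_sex_DSD")

  # orphan parent reference: loaded, cleared, warned
  path2 <- tempfile()
  writeLines(c("F1 idx ghost 0 1 2"), path2)
  expect_warning(ped2 <- read_ped(path2), "ghost")
  expect_equal(ped2$father_id, "")

  # duplicate sample id
  path3 <- tempfile()
  writeLines(c("F1 a 0 0 1 1", "F1 a 0 0 1 1"), path3)
  expect_error(read_ped(path3), "duplicate")

  # cyclic parentage
  path4 <- tempfile()
  writeLines(c("F1 a b 0 1 1", "F1 b a 0 1 1"), path4)
  expect_error(read_ped(path4), "cyclic")
})

test_that("ped round trip preserves structure and index flags", {
  ped <- mk_trio_ped()
  path <- tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_equal(back[order(back$sample_id), ],
               ped[order(ped$sample_id), ], ignore_attr = TRUE)
})

test_that("annotation table round trips and validates", {
  ann <- rbind(
    mk_annotation("k1", gnomad_af = 5.63e-05, cadd = 25.5,
                  tools = c(rep("pathogenic_like", 7), "missing", "missing"),
                  acmg_varsome = "B", acmg_franklin = "VUS"),
    mk_annotation("k2", gnomad_af = NA, cadd = NA))
  path <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_equal(back, ann[names(back)], ignore_attr = TRUE)
  # empty AF read back as missing, never zero
  expect_true(is.na(back$gnomad_af[2]))
  expect_equal(sum(unlist(back[2, paste0("tool_", tool_names())]) ==
                     "missing"), 9L)

  # AF outside [0,1] -> error
  bad <- ann; bad$gnomad_af[1] <- 1.5
  write_tsv_path <- tempfile(fileext = ".tsv")
  suppressWarnings(write_annotation_table(bad, write_tsv_path))
  expect_error(read_annotation_table(write_tsv_path), "\\[0,1\\]")

  # unknown tool column -> error
  lines <- readLines(path)
  lines[1] <- sub("tool_cadd", "tool_alphamissense", lines[1])
  path2 <- tempfile(fileext = ".tsv")
  writeLines(lines, path2)
  expect_error(read_annotation_table(path2), "tool")
})

test_that("pair score table parses ND as missing and enforces range", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("anchor_key\tpartner_key\tscore\teffect_class",
               "a\tp1\t0.9950\ttrue_digenic",
               "a\tp2\tND\t",
               "a\tp3\t0.6900\tmonogenic_modifier"), path)
  ps <- read_pair_scores(path)
  expect_equal(ps$score[1], 0.9950)
  expect_equal(ps$effect_class[1], "true_digenic")
  expect_true(is.na(ps$score[2]))
  expect_equal(ps$effect_class[2], "missing")

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("anchor_key\tpartner_key\tscore\teffect_class",
               "a\tp1\t1.2\ttrue_digenic"), path2)
  expect_error(read_pair_scores(path2), "outside")

  # round trip
  out <- tempfile(fileext = ".tsv")
  write_pair_scores(ps, out)
  expect_equal(read_pair_scores(out), ps, ignore_attr = TRUE)
})

test_that("gene panel and pathway map readers validate their contracts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "GLI3\tDSD", "NR5A1\tSF1"), path)
  panel <- read_gene_panel(path)
  expect_equal(nrow(panel), 2L)

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "GLI3\tDSD", "GLI3\tSF1"), path2)
  expect_error(read_gene_panel(path2), "duplicate")

  path3 <- tempfile(fileext = ".tsv")
  writeLines("gene\tcategory", path3)
  expect_error(read_gene_panel(path3), "empty")
})
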