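panel_small <- function() {
  data.frame(gene = c("GLI3", "FLNB", "COL9A3"),
             category = c("DSD", "DSD", "DSD"), stringsAsFactors = FALSE)
}

test_that("depth, consequence, MAF and panel predicates honour boundaries", {
  fc <- filter_config(panel = panel_small())
  # "a read depth of 20 or more" is inclusive
  expect_equal(apply_depth_filter(c(35, 20, 19, NA), fc),
               c(TRUE, TRUE, FALSE, FALSE))
  # all consequences except synonymous pass
  expect_equal(apply_consequence_filter(c("missense", "synonymous",
                                          "frameshift"), fc),
               c(TRUE, FALSE, TRUE))
  expect_warning(apply_consequence_filter("other", fc), "other")
  # MAF <= 0.01 inclusive; 5.63e-05 (a printed fixture frequency) passes
  m <- apply_maf_filter(c(5.63e-05, 0.01, 0.0101, NA), rep(NA_real_, 4),
                        rep("chr1", 4), rep("46,XY", 4), fc)
  expect_equal(m$pass, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(m$flag[4], "absent_from_gnomad")
  # karyotype-aware: XY frequency used on chrX for a 46,XY individual
  m2 <- apply_maf_filter(0.02, 0.004, "chrX", "46,XY", fc)
  expect_true(m2$pass)
  m3 <- apply_maf_filter(0.02, 0.004, "chrX", "46,XX", fc)
  expect_false(m3$pass)
  # panel: member passes, absent fails, anchor gene always passes
  expect_true(apply_panel_filter("GLI3", fc))
  expect_false(apply_panel_filter("BRCA1", fc))
  expect_true(apply_panel_filter("NR5A1", fc))
  fc_empty <- fc; fc_empty$panel <- fc$panel[0, ]
  expect_error(apply_panel_filter("GLI3", fc_empty), "empty")
})

mk_cascade_input <- function(n_background = 100) {
  # background designed to fail: synonymous, common, off-panel or shallow
  set.seed(42)
  fail_mode <- sample(c("synonymous", "common", "off_panel", "shallow"),
                      n_background, replace = TRUE)
  keys <- sprintf("chr1:%d:A:G", seq_len(n_background) * 10)
  variants <- data.frame(
    chrom = "chr1", pos = seq_len(n_background) * 10, ref = "A", alt = "G",
    variant_key = keys,
    gene_symbol = ifelse(fail_mode == "off_panel", "ZZZ9", "GLI3"),
    consequence = ifelse(fail_mode == "synonymous", "synonymous",
                         "missense"),
    scorable = TRUE, stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(n_background), function(i) {
    mk_annotation(keys[i], gene = variants$gene_symbol[i],
                  consequence = variants$consequence[i],
                  gnomad_af = if (fail_mode[i] == "common") 0.2 else 1e-4)
  }))
  geno <- mk_genotype("idx", keys, "het",
                      depth = ifelse(fail_mode == "shallow", 5L, 40L))
  # one planted rare missense panel variant
  planted_key <- "chr2:999:C:T"
  variants <- rbind(variants, data.frame(
    chrom = "chr2", pos = 999, ref = "C", alt = "T",
    variant_key = planted_key, gene_symbol = "FLNB",
    consequence = "missense", scorable = TRUE, stringsAsFactors = FALSE))
  ann <- rbind(ann, mk_annotation(planted_key, gene = "FLNB",
                                  gnomad_af = 1e-5))
  geno <- rbind(geno, mk_genotype("idx", planted_key, "het", 50L))
  list(variants = variants, genotypes = geno, annotations = ann,
       planted_key = planted_key)
}

test_that("cascade retains exactly the planted variant among failing background", {
  inp <- mk_cascade_input(100)
  ped <- mk_trio_ped()
  fc <- filter_config(panel = panel_small())
  fd <- run_cascade(inp$variants, inp$genotypes, inp$annotations, ped, fc)
  expect_equal(nrow(fd), 101L)
  expect_equal(fd$variant_key[fd$retained], inp$planted_key)
})

test_that("fail reasons are ordered depth, consequence, maf, panel", {
  ped <- mk_trio_ped()
  fc <- filter_config(panel = panel_small())
  v <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G",
                  variant_key = "chr1:1:A:G", gene_symbol = "GLI3",
                  consequence = "missense", scorable = TRUE,
                  stringsAsFactors = FALSE)
  a <- mk_annotation("chr1:1:A:G", gnomad_af = 0.5)
  g <- mk_genotype("idx", "chr1:1:A:G", "het", depth = 5L)
  fd <- run_cascade(v, g, a, ped, fc)
  expect_equal(fd$fail_reasons, "low_depth,maf")
  expect_false(fd$retained)

  # unannotated variant is decided, not dropped
  g2 <- mk_genotype("idx", "chr1:1:A:G", "het", depth = 40L)
  fd2 <- run_cascade(v, g2, a[0, ], ped, fc)
  expect_false(fd2$retained)
  expect_match(fd2$fail_reasons, "unannotated")

  # empty input yields an empty decision table
  fd3 <- run_cascade(v[0, ], g[0, ], a, ped, fc)
  expect_equal(nrow(fd3), 0L)
})

random_cascade_cohort <- function(n, seed) {
  set.seed(seed)
  keys <- sprintf("chr%d:%d:A:G", sample(1:22, n, TRUE), seq_len(n))
  genes <- sample(c("GLI3", "FLNB", "COL9A3", "OFFPANEL1", "OFFPANEL2"),
                  n, TRUE)
  cons <- sample(c("missense", "synonymous", "frameshift", "splice_site"),
                 n, TRUE)
  af <- ifelse(runif(n) < 0.2, NA,
               exp(runif(n, log(1e-6), log(0.5))))
  variants <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A",
                         alt = "G", variant_key = keys, gene_symbol = genes,
                         consequence = cons, scorable = TRUE,
                         stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(n), function(i) {
    mk_annotation(keys[i], gene = genes[i], consequence = cons[i],
                  gnomad_af = af[i])
  }))
  geno <- mk_genotype("idx", keys,
                      sample(c("het", "hom_alt"), n, TRUE),
                      depth = sample(0:60, n, TRUE))
  list(variants = variants, genotypes = geno, annotations = ann, af = af)
}

test_that("cascade equals an independent single-predicate brute-force filter", {
  ped <- mk_trio_ped()
  fc <- filter_config(panel = panel_small())
  ch <- random_cascade_cohort(200, seed = 7)
  fd <- run_cascade(ch$variants, ch$genotypes, ch$annotations, ped, fc)
  # independent oracle: a single flat predicate over the joined inputs
  oracle <- vapply(seq_len(nrow(ch$variants)), function(i) {
    depth <- ch$genotypes$depth[i]
    af <- ch$af[i]
    depth >= 20 &&
      ch$variants$consequence[i] != "synonymous" &&
      (is.na(af) || af <= 0.01) &&
      ch$variants$gene_symbol[i] %in% c(panel_small()$gene, "NR5A1")
  }, logical(1))
  m <- match(ch$variants$variant_key, fd$variant_key)
  expect_equal(fd$retained[m], oracle)
  # conservation: every input decided exactly once
  expect_equal(sum(fd$retained) + sum(!fd$retained), nrow(ch$variants))
})

test_that("relaxing thresholds never removes a retained variant", {
  ped <- mk_trio_ped()
  ch <- random_cascade_cohort(150, seed = 13)
  set.seed(99)
  for (i in 1:20) {
    d1 <- sample(5:40, 1); d2 <- sample(0:d1, 1)     # d2 <= d1
    m1 <- runif(1, 1e-4, 0.05); m2 <- runif(1, m1, 0.5)  # m2 >= m1
    strict <- filter_config(min_depth = d1, max_maf = m1,
                            panel = panel_small())
    lax <- filter_config(min_depth = d2, max_maf = m2,
                         panel = panel_small())
    r_strict <- run_cascade(ch$variants, ch$genotypes, ch$annotations, ped,
                            strict)
    r_lax <- run_cascade(ch$variants, ch$genotypes, ch$annotations, ped,
                         lax)
    expect_true(all(r_strict$variant_key[r_strict$retained] %in%
                      r_lax$variant_key[r_lax$retained]))
  }
})
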