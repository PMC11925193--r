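trio_genotypes <- function(idx_z = "het", fa_z = "hom_ref",
                           mo_z = "hom_ref", fa_d = 30L, mo_d = 30L,
                           key = "k1") {
  rbind(mk_genotype("idx", key, idx_z),
        mk_genotype("fa", key, fa_z, fa_d),
        mk_genotype("mo", key, mo_z, mo_d))
}

test_that("inheritance calls follow trio logic with depth-gated de novo", {
  ped <- mk_trio_ped()
  # carrier father, reference mother -> paternal
  g <- trio_genotypes(fa_z = "het")
  expect_equal(call_inheritance("k1", "idx", ped, g)$call, "paternal")
  g <- trio_genotypes(mo_z = "het")
  expect_equal(call_inheritance("k1", "idx", ped, g)$call, "maternal")
  # both reference at depth >= 20 -> de novo
  g <- trio_genotypes()
  expect_equal(call_inheritance("k1", "idx", ped, g)$call, "de_novo")
  # both carriers -> ambiguous
  g <- trio_genotypes(fa_z = "het", mo_z = "het")
  expect_equal(call_inheritance("k1", "idx", ped, g)$call,
               "biparental_ambiguous")
  # ungenotyped mother -> unresolved, never de novo
  g <- rbind(mk_genotype("idx", "k1", "het"),
             mk_genotype("fa", "k1", "hom_ref"))
  expect_equal(call_inheritance("k1", "idx", ped, g)$call, "unresolved")
  # reference parent at low depth cannot support de novo
  g <- trio_genotypes(fa_d = 10L)
  expect_equal(call_inheritance("k1", "idx", ped, g)$call, "unresolved")
})

test_that("de novo is never called when a parent genotype is unobserved", {
  set.seed(41)
  ped <- mk_trio_ped()
  for (i in 1:100) {
    fa_state <- sample(c("het", "hom_ref", "missing", "absent"), 1)
    mo_state <- sample(c("het", "hom_ref", "missing", "absent"), 1)
    fa_d <- sample(c(5L, 30L), 1); mo_d <- sample(c(5L, 30L), 1)
    g <- mk_genotype("idx", "k1", "het")
    if (fa_state != "absent") g <- rbind(g, mk_genotype("fa", "k1", fa_state, fa_d))
    if (mo_state != "absent") g <- rbind(g, mk_genotype("mo", "k1", mo_state, mo_d))
    call <- call_inheritance("k1", "idx", ped, g)$call
    fa_observed <- fa_state == "het" ||
      (fa_state == "hom_ref" && fa_d >= 20L)
    mo_observed <- mo_state == "het" ||
      (mo_state == "hom_ref" && mo_d >= 20L)
    if (call == "de_novo") {
      expect_true(fa_observed && mo_observed)
      expect_true(fa_state == "hom_ref" && mo_state == "hom_ref")
    }
  }
})

test_that("carrier status classifies relatives for the anchor variant", {
  ped <- mk_trio_ped(mo_affection = "asymptomatic")
  g <- rbind(mk_genotype("mo", "anchor", "het"),
             mk_genotype("fa", "anchor", "hom_ref"))
  cs <- carrier_status(ped, "anchor", g)
  expect_equal(cs$status[cs$sample_id == "mo"], "carrier")
  expect_equal(cs$status[cs$sample_id == "fa"], "non_carrier")
  expect_equal(cs$status[cs$sample_id == "idx"], "unknown")
})

test_that("co-segregation consistency matches a brute-force enumeration", {
  # model-family: father anchor-only asymptomatic, mother neither,
  # index both and affected -> consistency 1
  ped <- mk_trio_ped()
  g <- rbind(mk_genotype("fa", "anchor", "het"),
             mk_genotype("mo", "anchor", "hom_ref"),
             mk_genotype("idx", "anchor", "het"),
             mk_genotype("fa", "partner", "hom_ref"),
             mk_genotype("mo", "partner", "hom_ref"),
             mk_genotype("idx", "partner", "het"))
  cs <- cosegregation_consistency("anchor", "partner", ped, g, "idx")
  expect_equal(cs$n_evaluable, 2L)
  expect_equal(cs$consistency, 1.0)
  expect_length(cs$counterexamples, 0L)

  # an asymptomatic double carrier is a counterexample
  g2 <- g
  g2$zygosity[g2$sample_id == "fa" & g2$variant_key == "partner"] <- "het"
  cs2 <- cosegregation_consistency("anchor", "partner", ped, g2, "idx")
  expect_lt(cs2$consistency, 1)
  expect_equal(cs2$counterexamples, "fa")

  # singleton index: nothing to evaluate
  solo <- ped[ped$sample_id == "idx", ]
  cs3 <- cosegregation_consistency("anchor", "partner", solo, g, "idx")
  expect_equal(cs3$n_evaluable, 0L)
  expect_true(is.na(cs3$consistency))

  # oracle: literal re-derivation over random family configurations
  set.seed(51)
  for (i in 1:30) {
    n_rel <- sample(2:5, 1)
    rel <- data.frame(
      sample_id = paste0("r", seq_len(n_rel)), family_id = "F",
      father_id = "", mother_id = "", karyotype = "46,XY",
      affection = sample(c("asymptomatic", "severe_DSD", "POI", "unknown"),
                         n_rel, TRUE),
      phenotype_notes = "", is_index = FALSE, stringsAsFactors = FALSE)
    fam <- rbind(rel, mk_trio_ped()[3, ])
    gg <- do.call(rbind, lapply(fam$sample_id, function(s) {
      rbind(mk_genotype(s, "a", sample(c("het", "hom_ref", "missing"), 1)),
            mk_genotype(s, "p", sample(c("het", "hom_ref", "missing"), 1)))
    }))
    got <- cosegregation_consistency("a", "p", fam, gg, "idx")
    # brute force: enumerate relatives, apply the digenic rule literally
    exp_eval <- 0L; exp_cons <- 0L
    for (s in rel$sample_id) {
      za <- gg$zygosity[gg$sample_id == s & gg$variant_key == "a"]
      zp <- gg$zygosity[gg$sample_id == s & gg$variant_key == "p"]
      aff <- rel$affection[rel$sample_id == s]
      if (aff == "unknown" || za == "missing" || zp == "missing") next
      exp_eval <- exp_eval + 1L
      both <- za == "het" && zp == "het"
      is_aff <- aff %in% c("severe_DSD", "POI")
      if ((both && is_aff) || (!both && !is_aff)) exp_cons <- exp_cons + 1L
    }
    expect_equal(got$n_evaluable, exp_eval)
    expect_equal(got$n_consistent, exp_cons)
  }
})

test_that("partially affected classes are excluded from the denominator", {
  ped <- mk_trio_ped(fa_affection = "mild_DSD")
  g <- rbind(mk_genotype("fa", "anchor", "het"),
             mk_genotype("fa", "partner", "hom_ref"),
             mk_genotype("mo", "anchor", "hom_ref"),
             mk_genotype("mo", "partner", "hom_ref"),
             mk_genotype("idx", "anchor", "het"),
             mk_genotype("idx", "partner", "het"))
  # father: anchor-only yet mildly affected -> counterexample by default
  strict <- cosegregation_consistency("anchor", "partner", ped, g, "idx")
  expect_equal(strict$counterexamples, "fa")
  # treated as incomplete penetrance when mild_DSD is partially_affected
  lenient <- cosegregation_consistency("anchor", "partner", ped, g, "idx",
                                       partially_affected = "mild_DSD")
  expect_equal(lenient$n_evaluable, 1L)
  expect_equal(lenient$consistency, 1.0)
})

test_that("compound het scan phases by parental origin", {
  ped <- mk_trio_ped()
  v <- data.frame(variant_key = c("f1", "f2"), gene_symbol = "FLNB",
                  stringsAsFactors = FALSE)
  # one paternal, one de novo -> confirmed trans
  g <- rbind(trio_genotypes(key = "f1", fa_z = "het"),
             trio_genotypes(key = "f2"))
  ch <- compound_het_scan("FLNB", v, g, ped, "idx")
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$phase, "confirmed_trans")
  # both paternal -> cis, not flagged
  g2 <- rbind(trio_genotypes(key = "f1", fa_z = "het"),
              trio_genotypes(key = "f2", fa_z = "het"))
  expect_equal(nrow(compound_het_scan("FLNB", v, g2, ped, "idx")), 0L)
  # no parents genotyped -> possible
  g3 <- rbind(mk_genotype("idx", "f1", "het"),
              mk_genotype("idx", "f2", "het"))
  ch3 <- compound_het_scan("FLNB", v, g3, ped, "idx")
  expect_equal(ch3$phase, "possible")
  # fewer than two hets -> nothing
  expect_equal(nrow(compound_het_scan("FLNB", v, g3[1, ], ped, "idx")), 0L)
})
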