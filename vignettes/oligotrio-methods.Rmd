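---
title: "Methods: anchor-gene oligogenic variant prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-gene oligogenic variant prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Heterozygous variants in *NR5A1* (steroidogenic factor 1, SF-1) are
associated with a remarkably broad phenotypic spectrum in 46,XY
individuals — from asymptomatic carriers through mild hypospadias to
complete gonadal dysgenesis with opposite-sex phenotype. One proposed
explanation is oligogenic inheritance: the *NR5A1* variant is necessary but
not sufficient, and the phenotype is shaped by additional rare variants in
developmentally related genes. `oligotrio` implements, as a tested and
reusable pipeline, the family-exome workflow used to investigate this
hypothesis: rare-variant filtering anchored on the family's *NR5A1* variant,
pairing of each surviving candidate with the anchor under a
pair-pathogenicity score, a dual-criterion candidate selection, trio-based
segregation analysis, and cohort-level recurrence summaries. The anchor
gene is a parameter throughout (`default_anchor_gene()` returns `"NR5A1"`),
so the same machinery applies to any anchor-gene rare-disease design.

## Pipeline model

### Filter cascade

Variants observed in an index case (non-reference, non-missing genotype)
pass four ordered filters:

1. **Depth** — read depth `>= 20` (inclusive) in the index sample.
2. **Consequence** — every predicted consequence except synonymous.
3. **Population frequency** — gnomAD MAF `<= 0.01` (inclusive). For a
   46,XY individual and a sex-chromosome variant the XY-specific frequency
   is compared when available (`karyotype_aware_maf`). A variant absent
   from gnomAD passes under a rarity presumption, flagged
   `absent_from_gnomad` for audit.
4. **Panel** — membership in a DSD/SF-1 gene panel; the anchor gene always
   passes.

Every decision is emitted with per-filter flags and ordered fail reasons;
a variant with no annotation row fails with reason `unannotated` rather
than disappearing. Filters gate on the index only; family genotypes are
carried to the segregation stage untouched.

Two operationalisations here are package decisions because the procedure
they formalise was described only qualitatively: the karyotype-aware rule
(compare the XY allele frequency for sex-chromosome variants in 46,XY
individuals, else the overall frequency) and index-only depth gating.

### Pair scores and criterion 1

Pair-pathogenicity scores are *ingested*, not computed: they are
probabilities in [0, 1] that an (anchor variant, partner variant)
combination is disease-causing, as produced by a VarCoPP-style trained
predictor. Two nested cutoffs apply, with boundary semantics that follow
the predictor's published wording: a combination is *disease-causing* when
its score is strictly above 0.4575, and lies in the *99.9% confidence
zone* when the score is at least 0.85 (inclusive). Criterion 1 of
candidate selection is confidence-zone membership. A missing score
(`ND`, no prediction) satisfies neither and is flagged.

For synthetic runs a clearly labelled surrogate scorer
(`surrogate_pair_score()`, a fixed logistic over partner CADD, partner
allele frequency, panel category and anchor consequence severity) is
available; it is not a reimplementation of the trained random forest, and
its outputs carry the metadata tag `surrogate_logistic_v1`.

### Consensus and criterion 2

Criterion 2 retains a variant on its own evidence, regardless of any pair
score: its resolved ACMG class is VUS, likely pathogenic or pathogenic, or
at least 7 of 9 in-silico tools (PolyPhen-2, Panther, SNPs&GO, CADD, SIFT,
Provean, REVEL, MutationTaster, M-CAP) call it pathogenic-leaning.
Three aggregation choices are package decisions where the source procedure
is silent:

* the vote denominator is fixed at nine — a tool with no call counts
  against the variant (conservative and literal to "seven out of nine");
* "uncertain" tool calls count toward the seven, since the qualifying
  verdicts include VUS;
* when the two ACMG platforms disagree, the more pathogenic class wins
  under the ordering B < LB < VUS < LP < P.

The consensus is provably monotone: upgrading any tool call or ACMG class
can never cause criterion 2 to flip from true to false (property-tested,
and checked exhaustively over all 3^9 tool-call configurations).

### Selection and phenotype rejection

A pair is retained when criterion 1 or criterion 2 holds and the partner
is not phenotype-rejected. The manual literature review that rejected
variants "lacking an association with the observed phenotype" is modelled
as per-case deny lists (gene or variant granularity, empty by default) —
literature mining is out of scope by design.

A case is *oligogenic-positive* when at least one pair is retained.
Anchors that the external predictor cannot pair — symbolic/structural
alleles such as a whole-gene deletion, a large duplication, or a
homozygous anchor treated as monogenic by the predictor — produce no
pairs and a case-level `anchor_not_pairable` flag; their candidate rows
are still reported (retained = FALSE) so record counts are conserved. The
packaged fixture encodes three such cases. Whether criterion 2 alone can
retain a variant with no pair score at all is an interpretation adopted
here (supported by the fixture's NR1H2 row, included for its VUS status
despite no prediction); it applies only when the case's anchor is
pairable.

### Segregation

Inheritance calls use trio logic: a carrier parent gives
maternal/paternal, both carriers give `biparental_ambiguous`, and
`de_novo` requires both parents genotyped reference at depth `>= 20` at
the site (the cascade's depth convention, reused deliberately so there is
a single depth parameter). An ungenotyped or low-depth parent yields
`unresolved`, never `de_novo` — this is enforced by a property test.

Co-segregation of a retained pair is summarised by a *consistency*
statistic: the fraction of evaluable relatives for whom (carries both
variants ⇒ affected) and (carries at most one ⇒ unaffected). This
statistic is this package's formalisation of the qualitative
family-segregation assessment in the source procedure, and outputs label
it as such. Mild phenotypes in single-variant carriers would count as
counterexamples under the strict rule; the `partially_affected` argument
excludes configurable affection classes from the denominator, reflecting
the view that such relatives indicate incomplete penetrance rather than
contradiction. Modifier-class pairs (one major gene, one modifier) are
not expected to reach consistency 1 — an affected relative carrying the
anchor without the modifier is biologically expected and is reported as a
counterexample, not an error.

Compound heterozygosity is scanned per gene from parental transmission
only (no read-backed phasing): two heterozygous index variants tracing to
different origins (different parents, or one parental and one de novo)
are `confirmed_trans`; unresolvable configurations are `possible`.

### Cohort summaries

Recurrence is summarised at two levels: identical variants retained in two
or more unrelated cases, and genes with retained variants in two or more
unrelated cases. "Unrelated" means distinct family identifiers — two
affected cousins in one family never form a cross-case cluster. In
fixture mode variant identity is gene + HGVS-c, because the source tables
print no genomic coordinates; in VCF mode it is the normalized
`chrom:pos:ref:alt` key. Mean CADD is computed over retained variants with
a score, excluding `ND` from numerator and denominator. Pathway overlap
against the anchor gene uses exact set intersection over a user-supplied
static gene-to-pathway map (no live database access, for
reproducibility); the packaged `synthetic_pathway_map.tsv` is a toy map,
labelled synthetic, built so that 14 fixture genes (~30%) share a pathway
with the anchor.

On the packaged fixture the recurrence recounts reproduce the printed
per-gene and per-variant clusters exactly. Two documented discrepancies
of the printed tables are preserved rather than suppressed: enumeration
yields a ninth recurrent gene (SRA1, two cases with different variants)
beyond the eight listed, and the printed main-text tables cover 29 index
cases and 68 candidate rows while cohort-level headline totals include an
appendix-only case — cohort totals are therefore validated against the
recomputed fixture (21 of 29 printed cases positive), not forced to the
headline numbers.

## Variant normalization

Multiallelic records are decomposed into one alternate allele per variant,
and shared REF/ALT context bases are trimmed (trailing first, then
leading, advancing the position) to a canonical `chrom:pos:ref:alt` key.
Trimming is idempotent, and for variants whose allele edges differ the key
is invariant to padding with shared context. Full left-alignment of
indels in repeat context requires the reference sequence and is *not*
performed; users supplying VCFs should pre-normalise with standard tools
if their call sets contain unnormalised homopolymer indels. Symbolic
alleles (`<DEL>`, `<DUP>`, breakends) are parsed, flagged non-scorable and
excluded from pair building.

## The synthetic cohort generator

`simulate_cohort()` generates a fully in-silico cohort — per-family VCFs,
a cohort PED, annotation and pair-score sidecars, and a ground-truth
JSON — so every stage is testable without downloads. What it emulates:

* **Stated cohort structure.** Defaults are 30 families with trio
  pedigrees (quartet/extended shapes available), heterozygous anchors
  transmitted from an asymptomatic carrier parent or de novo (mixed
  0.4/0.4/0.2), and planted partner variants inherited from the other
  parent or de novo (10%).
* **Planted recoverability.** Partners are non-synonymous panel-gene
  variants with MAF at most 0.01 and depth floored at 20, pathogenic-
  leaning annotations (VUS/VUS, 7 + 2 qualifying tool calls) and pair
  scores uniform on [0.85, 1] — by construction they pass the cascade and
  criterion 1.
* **Background.** Poisson-distributed background variants per index (rate
  0 by default; set 50 for a realistically noisy screen) with log-uniform
  allele frequencies on [1e-6, 0.05] (so a closed-form fraction
  log(1e4)/log(5e4) ≈ 0.85 survives the MAF filter), 30% synonymous,
  benign annotations and pair scores uniform on [0, 0.4575].
* **Penetrance.** Under `true_digenic`, affected iff anchor plus at least
  one partner (so carrier parents are asymptomatic); under
  `monogenic_modifier`, every anchor carrier is affected, upgraded from
  mild to severe by a partner.
* **Depth.** Negative-binomial per (sample, site), mean 60, size 8 —
  typical exome coverage with realistic overdispersion.

What it does **not** emulate: linkage disequilibrium, recombination,
sequencing error, population stratification, CNVs, or the feature
correlations a trained pair predictor exploits. A green recovery test
therefore establishes that the pipeline's plumbing, thresholds and
segregation logic are correct against planted truth — not that the
external predictor's scores are biologically valid, which is out of scope
by design (scores are inputs).

Determinism: all randomness flows from the single config seed, files
contain no timestamps, and two runs with the same seed are byte-identical
(hash-compared in tests).

## Numerical and degenerate-input choices

* Boundary semantics: depth and MAF inclusive; 0.4575 strict; 0.85
  inclusive — each follows the quoted wording of its source.
* Zero evaluable relatives give an undefined (NA) consistency, never 0.
* All-missing CADD gives an undefined mean.
* Depth 0 forces a missing genotype; a missing genotype never supports
  any inheritance call.
* Empty cohorts/VCFs yield empty, well-typed tables, never errors.
* The fixture keys variants by gene + HGVS-c verbatim; coordinate-level
  identity is left to users supplying VCFs (no HGVS-to-genomic liftover).

## Known limitations

* No quality-score (GQ/QUAL), region or CNV filtering; the fixture's
  whole-gene deletion is representable but not analysed.
* No linkage analysis, kinship verification or X-inactivation modelling.
* Pair scoring is anchor × partner only, matching the bi-locus design of
  the upstream predictor; partner × partner combinations are out of
  scope.
* Statistical enrichment of recurrence is deliberately absent — at
  cohorts of this size the analysis is descriptive.
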