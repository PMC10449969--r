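---
title: "Methods: rare-variant prioritization and summary-statistic burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant prioritization and summary-statistic burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varburden)
```

# The setting

`varburden` targets the study design where a few dozen cases with a shared,
probably monogenic-heterogeneous phenotype are exome-sequenced and compared
against a population reference that is only available as per-site summary
statistics (allele count AC, allele number AN, homozygote count nhom; the
gnomAD exome convention, N = 125,748 individuals by default). The question
is not "which variant is causal" but "which genes, and which biological
processes, accumulate more rare deleterious variation in cases than
expected".

The chain has four stages: per-call genotype QC, variant prioritization,
gene-set overrepresentation, and a per-gene collapsing (burden) test under
dominant and recessive inheritance models. Each stage is exposed as plain
functions returning classed S3 objects with `print`/`summary` methods;
`run_pipeline()` wires them together.

# Genotype QC: the allele ratio

Amplicon-based exome platforms produce a non-trivial rate of artifactual
calls recognizable by skewed allelic balance. For a call with alternate
read count $AC$ and site depth $CD$, the allele ratio is

$$AR = AC / CD.$$

A true heterozygote should sit near 0.5, a true homozygote near 1. Calls
are kept when $0.35 \le AR \le 0.65$ (het) or $AR \ge 0.9$ (hom), all
bounds inclusive; a call at exactly 0.35 passes. Zero-depth calls cannot be
QC'd and are discarded with a logged reason. The band is a tunable
`ar_bounds()` object; the defaults are the conventional ones for this
platform class. The QC is a read-support check, not a functional one, so by
default it applies to indel calls as well as SNVs
(`prioritization_criteria(ar_applies_to_indels = )` restricts it to SNVs).

# Prioritization cascade

Variant-level rules, applied before the per-call QC for reporting purposes
(the predicates are pure and commute; the cascade order only fixes which
filter an exclusion is *attributed* to in the attrition ledger):

* **SNVs** need a unanimous deleterious consensus — SIFT ≤ 0.05 ("D"),
  PolyPhen2 ≥ 0.909 (the "probably damaging" score floor), MutationTaster
  "deleterious" — fewer than 2 PredictSNP2 component tools calling the
  variant benign/tolerated, and reference-population MAF < 0.001 (strict).
* **Indels** are kept on MAF < 0.001 alone: their in-silico
  deleteriousness scores are not comparable to the SNV consensus.
* A **missing score fails** any filter that needs it. Unannotated variants
  are overwhelmingly alignment noise in this setting, and letting them
  through would flood the collapsed gene list; the attrition ledger makes
  the cost visible. The one deliberate exception is **missing MAF, read as
  0**: absence from reference populations is evidence of rarity, and novel
  variants must be able to pass a rarity filter.
* **Recurrence**: after QC, a variant carried by more than 5 distinct
  samples (10% of a 50-case cohort; individuals, not alleles) is removed
  outright, carriers included. In a rare-disease cohort of unrelated
  probands, a site recurring that often is far more plausibly a platform
  artifact than a shared causal allele.

All thresholds are inclusive or strict exactly as written above; the
boundaries are test cases. Survivors collapse to a deduplicated gene list.
The attrition ledger satisfies input = survivors + per-filter removals with
first-failing-filter attribution.

# Overrepresentation

For a collapsed list of $n$ genes against a term of $K$ genes in an
explicit background universe of $M$, the overlap $k$ is tested with
Fisher's exact test on $[[k, n-k], [K-k, M-n-K+k]]$. The test is two-sided
by default (summing all tables with point probability at most the observed
one) because *under*-representation is biologically informative too; a
one-sided mode is a flag. Direction is the sign of $k - nK/M$, with ties
(k exactly at expectation) reported as "under". BH FDR runs across the
terms tested; `bh_adjust(p, m_total)` also supports adjusting a reported
subset against a larger family. The background never defaults to anything
implicit: it is either supplied or taken as all genes occurring in the
gene-set collection, and genes outside it are dropped from terms with a
count. Empty terms get $p = 1$, direction "under", fold undefined.

# The burden test

## Qualifying variants

Burden criteria are deliberately looser than the prioritization consensus
(they mirror collapsing-test practice): SNV, SIFT ≤ 0.05, PolyPhen2 ≥ 0.8,
MAF < 0.01, and carrier-call depth > 10 (exclusive). Depth is a property of
the call, so a variant may qualify in one sample and not another.

## Case side

Per gene, each sample with a qualifying call is classified once: *hom* if
any homozygous-alt call; else *CH* (putative compound heterozygote) if het
at ≥ 2 distinct sites; else *het*. Dominant carriers = het + hom;
recessive carriers = CH + hom. Phase is unknown, so "CH" means "two or
more distinct het sites" and nothing stronger — a cis configuration cannot
be excluded and is not claimed.

## Control side

The control cohort exists only as summary counts, so carrier numbers must
be approximated:

* **Dominant**: the gene's summed control AC, each allele assumed to sit in
  a distinct individual, capped at the control N. For variants this rare
  the collision probability is negligible, and the approximation errs
  conservative (it can only overstate control carriers).
* **Recessive**: two constructions. `reported_hom` uses the summed nhom —
  exact for homozygotes but blind to control compound hets, hence
  anti-conservative. `expected_biallelic` estimates biallelic carriers
  under site independence as $\mathrm{round}(N (1 - \prod_i(1-f_i))^2)$
  with $f_i = AC_i/AN_i$, treating an individual's two haplotypes as
  independent draws; it dominates `reported_hom` whenever frequencies are
  positive. Neither is exact; both are reported as what they are, and no
  recessive claim in the package's validation rests on reproducing
  published recessive p-values (see Limitations).

**Which control sites enter the sums** matters more than it looks. If the
per-gene control AC is summed only over sites the cases happened to carry,
the control margin is conditioned on case carriers and the test becomes
sharply anti-conservative in the sparse regime: a null gene with a single
carrier at a single site of frequency 5×10⁻⁴ gets a one-sided p of 0.049
essentially by construction, and the per-gene type-I rate approaches the
probability that a null gene is carried at all (~0.4 under the default
simulation). The collapsing-test methodology this package follows instead
builds a *control-side* qualifying set: all of the gene's sites passing the
qualifying rules in the control population, whether or not any case carries
them — which is also the only way to obtain control ACs in the thousands
against case ACs in the tens, the regime published burden tables show. The
package therefore prefers a gene-annotated control summary (TSV with an
eighth `gene` column): control sums then run over every control site of the
gene that is an SNV with control frequency below the MAF ceiling (plus the
functional score rules where the site is also present, hence annotated, in
the case table). With a bare summary the case-derived fallback is used and
documented as anti-conservative for sparsely hit genes. Under the
gene-annotated construction the same singleton gene gets p = 0.396 and the
simulated per-gene type-I rate at α = 0.05 is ≈ 0.014 — conservative, as a
one-sided exact test should be.

## Test and adjustment

Each 2×2 table (cases/controls × carrier/non-carrier) is tested one-sided
for carrier excess in cases: the upper hypergeometric tail
$P(X \ge a)$ conditioning on the margins. An all-zero table returns 1.
BH FDR is applied per model across the genes tested; genes with no
qualifying case variant are excluded from testing *and* from the family
size m. Published tables rarely state their effective m, so
`implied_m(p, fdr)` recovers it from reported p/FDR pairs
(median of $\mathrm{fdr}_i \cdot \mathrm{rank}_i / p_i$), and
`summary()` of a scan prints it.

# The synthetic-cohort generator

`cohort_sim_spec()` fixes the generative model; everything downstream is a
deterministic function of the spec (seed mandatory, byte-identical reruns).
It emulates the features of real data the filters address, and only those:

* A catalogue of genes × sites; control allele frequency $f$ per site
  (default 5×10⁻⁴ — rare enough to pass every MAF filter, common enough to
  yield control ACs of ~126 per site at N = 125,748). The control summary
  is computed *deterministically* — AC = round(2Nf), AN = 2N,
  nhom = round(Nf²) — so any case-vs-control discrepancy is attributable to
  case sampling alone; a binomially sampled mode exists behind a flag.
* Case genotypes: per-site carrier probability
  $\min(1, m_g \cdot (1-(1-f)^2))$ with a per-gene multiplier $m_g$
  (1 = null gene; the default study condition for power checks is a 50-case
  cohort, 200 genes × 10 sites, multiplier 20 on 3 genes). Genes flagged
  for recessive spiking additionally plant compound-het pairs at rate
  $\min(1, m_g q^2)$, $q$ the gene's carrier haplotype frequency.
* Read support: depths uniform on [20, 100] so the depth rule passes by
  default (a low-depth fraction down to depth 7–10 exercises it); clean het
  calls draw AR in [0.40, 0.60], clean homs in [0.95, 1], and the rounding
  to integer read counts provably stays inside the inclusive QC band for
  every depth ≥ 7. Artifact calls (a configurable fraction) draw AR
  strictly outside the band, on either side.
* Recurrent artifact sites are planted in more than `recurrence_max`
  samples with clean balance and damaging-looking annotations — exactly the
  pathology the recurrence filter exists for — and are absent from the
  control summary (novel artifacts).
* Annotations: a site passes all functional score filters with probability
  `p_damaging` (scores then drawn inside the passing ranges, otherwise
  outside them).

The generator returns ground-truth labels computed from what it actually
emitted (per-call artifact flags, per-variant survival of the cascade,
per-gene spike models), so filter tests compare against bookkeeping, not
intent. What the generator does **not** model: linkage disequilibrium,
population structure, base-level sequencing error, coverage differences
between case and control platforms, and annotation disagreement between
case and control sides. Tests passing on this generator therefore validate
the *inference machinery* — they do not certify robustness to confounding
in real cohorts.

# Numerical and design choices

* Variant identity is the tuple (chrom, pos, ref, alt), 1-based, after
  normalization; the reader validates biallelic normalized input but never
  normalizes (multiallelic records are a hard error instructing
  pre-splitting, as re-normalizing silently would hide upstream problems).
* One-sided Fisher is computed directly as the upper hypergeometric tail
  (`stats::phyper`); the two-sided test delegates to `stats::fisher.test`'s
  probability-mass rule. Both are checked in the test suite against an
  independent exhaustive enumeration oracle over all tables with total
  ≤ 200, and BH against a literal step-up implementation.
* Ties: results sort by p then gene/term id, so output is deterministic
  under input reordering.
* MNV records (equal-length multi-base alleles) are typed but rejected by
  the prioritization cascade: the upstream contract is that MNVs are split
  before entry.
* Test-suite and acceptance problem sizes (50 spike-in replicates at
  200 genes; 200 null replicates at 50 genes; 10⁴-table oracle sweeps)
  were chosen as the smallest sizes at which the binomial error bars on
  the measured rates are decisively inside the acceptance margins.

# Limitations

* The recessive control construction is approximate in both modes;
  published recessive p-values from comparable analyses are not
  reproducible from their printed counts under either construction, which
  is why the package's validation anchors on the dominant model only.
* The dominant control approximation (alleles ≈ carriers) breaks down if a
  gene's control AC approaches the cohort size; the cap makes the failure
  graceful, not correct. At MAF < 0.01 per site this is immaterial.
* With a bare (gene-less) control summary the burden test inherits the
  case-conditioning bias described above; prefer gene-annotated summaries.
* No relatedness, ancestry or coverage adjustment anywhere: the test
  compares raw carrier rates. A 50-vs-125,748 comparison is intrinsically
  asymmetric, and systematically higher case coverage or divergent
  ancestry will inflate significance in real data.
* The enrichment stage treats terms as flat sets — no ontology graph
  propagation, no term hierarchy.
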