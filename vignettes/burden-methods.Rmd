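---
title: "Methods: collapsing burden tests against reference panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsing burden tests against reference panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinburden)
```

## The study design this package serves

Extreme-phenotype designs concentrate genetic signal by restricting cases to
the severe end of a trait distribution and accept a structural compromise:
the case cohort is small (here, 97 genomes with a 34-case severe subset and
a 147-case replication cohort) and the comparison group is not a matched
control series but an external population reference panel (a 1000-sample
national panel, or population-specific allele frequencies from a large
aggregation database). The unit of inference is therefore a 2×2 count table
per gene — qualifying alleles in cases versus the panel — rather than a
per-sample regression. Everything in this package is organised around
making that table exactly, testing it, and guarding the many filtering
boundaries that decide which alleles enter it.

## The collapsing burden model

For one gene, one variant class and one panel, let $a$ be the sum of
alternate-allele counts over qualifying sites in cases, $b = 2N_\text{case} - a$,
$c$ the sum of panel alternate-allele counts at the same sites and
$d = 2N_\text{panel} - c$. The test statistic is the Pearson chi-squared on
$(a, b; c, d)$ with one degree of freedom and no continuity correction; the
effect estimate is $\widehat{OR} = ad/bc$ with the Wald interval
$\exp(\ln \widehat{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$.

Assumptions worth stating explicitly:

* **Allele independence (Hardy–Weinberg).** Collapsing alleles over
  chromosomes treats the $2N$ chromosomes as independent Bernoulli draws.
  Inbreeding, relatedness, or strong LD between qualifying sites would
  overdisperse the counts and anticonservative p-values follow.
* **Panel comparability.** The panel's allele number is taken at face value
  per site; sites absent from a panel of declared size contribute zero
  alleles against the full denominator. Coverage differences between cohort
  and panel are not modelled.
* **No covariate adjustment.** There is deliberately no regression layer —
  the design has no shared covariates between a case VCF and a frequency
  table. Ancestry mismatch must be handled upstream (by choosing the right
  panel), not by this test.

The literature name for this procedure ("Wald chi-squared" collapsing)
under-specifies the cell construction; this implementation fixes it as
above and documents the choice rather than guessing at alternatives. Two
counting units are exposed: **alleles** (chromosomes, the default for SNV
collapsing) and **carriers** (samples, used for structural variants, where
published tables report per-sample carrier frequencies). The same
`burden_test()` serves both; only the inputs change.

### Numerical conventions

* **Zero cells.** The odds ratio and its interval use Haldane–Anscombe
  corrected cells (+0.5 on all four) whenever any cell is zero; the
  chi-squared always uses the raw cells. This keeps the p-value and the
  effect estimate decoupled: the correction stabilises the estimate without
  manufacturing or destroying significance.
* **Degenerate tables.** A table with an empty margin (no alternate alleles
  anywhere, or no reference alleles anywhere) carries no information:
  p = 1 by convention, OR reported missing, never enriched. This avoids
  fabricated significance for SVs absent from both cohorts.
* **Enrichment and replication.** `enriched` requires both p below α
  (default 0.05, configurable) and OR > 1. A gene replicates when enriched
  against at least one panel in each of two cohorts, within the same
  variant class. No multiple-testing adjustment is applied by default —
  the source analyses report unadjusted p-values — but Bonferroni and
  Benjamini–Hochberg columns are available behind a flag.
* **Ordering.** Results sort by p ascending, then OR descending, then gene
  symbol, so reports are reproducible under ties.
* **Fisher option.** `burden_test(method = "fisher")` exists for sparse
  tables; the test suite checks that its p-values agree with the
  chi-squared in rank order (Spearman ≥ 0.99) on tables with all cells ≥ 5.

### Filtering boundaries, taken literally

Every threshold is applied with the boundary semantics of the text that
defines it, and each boundary has a regression test:

| quantity | rule | boundary |
|---|---|---|
| rarity | MAF < 0.01 in *every* panel | 0.01 exactly is common |
| damage | CADD phred > 20 | 20.0 is non-damaging; missing is non-damaging |
| pLI intolerance (genes) | pLI ≥ 0.9 | 0.9 qualifies |
| LOEUF constraint (genes) | LOEUF < 0.5 | 0.5 fails |
| SV constrained region | pLI > 0.9 **and** LOEUF bin < 2 | 0.9 fails, bin 2 fails, missing bin fails |
| SV size window | 1 kb ≤ length ≤ 1 Mb | both ends inclusive; oversized calls survive only via known-SV concordance |
| blacklist artifact | coverage > 0.66 dropped | exactly 0.66 kept |
| known-SV concordance | reciprocal overlap ≥ 0.99 | 0.99 kept |
| ultra-rare SV | reference carrier frequency ≤ 0.001 | inclusive; absent = 0 |
| chronic inclusion | TFI ≥ 48 | inclusive |
| severe subset | THI ≥ 58 | inclusive |

Two of these required a decision. The severity cutoff appears in the source
material both as "THI > 58" and "THI ≥ 58"; the tabulated cohort definition
uses ≥ 58, and the table is the operational definition, so ≥ 58 it is. The
ultra-rare cutoff is never defined numerically in the source; 0.001 is the
frequency resolution of a 1000-sample carrier panel (one carrier), and the
flag is inclusive at the boundary so a single panel carrier still counts as
ultra-rare. The per-cohort frequency floor 1/(2N) (`cohort_maf_floor()`) is
computed as an annotation only — whether the original analysis used it to
exclude variants is not stated, so excluding on it would be an invention.

The 66% blacklist rule is read as *one-sided coverage of the SV* (what
fraction of the call is inside artifact-prone regions), while the 99%
known-SV rule is read as *reciprocal* overlap — the phrasing of the two
rules differs in exactly this way, and reciprocal matching is the standard
for SV identity while one-sided coverage is the standard for artifact
masking. Coverage is computed on the union of regions, so fragmented or
overlapping region files give identical answers.

### The simplified ACMG rubric

Full dosage-sensitivity scoring needs curated resources that are out of
scope; what the pipeline needs is a deterministic, configurable mapping
from evidence flags to classes 1–5 with classes 3–5 retained. The shipped
rubric is three ordered rules — benign-region overlap → class 2 (and
dropped), documented dosage-sensitive gene loss → class 4, constrained-gene
overlap → class 3, default 2 — expressed as a data frame the user can
replace. Benign evidence outranks everything, mirroring the practice of
filtering benign/likely-benign overlaps before prioritization. The rubric
is declarative so any alternative rule set is equally testable.

## The synthetic-data generator

The generator exists so that calibration, power and every filter can be
exercised against known ground truth; its defaults are the study conditions
of the motivating design: 97 cases, 34 severe, 147 replication, one
1000-sample panel, reference site frequencies from Beta(0.2, 50) (median
far below 1%, ~88% of mass below the rarity cutoff), comorbidity
probabilities conditional on severity chosen so the severe and pooled
prevalences match the published clinical table (e.g. hyperacusis 0.94
severe / 0.56 non-severe), and a recurrent deletion planted at carrier
frequency 0.216 in cases versus 0.017 in the reference.

**Planting enrichment on the OR scale.** For an enriched gene the
gene-level collapsed case frequency is solved from the odds-ratio identity
$f_\text{case} = OR \cdot f / (1 - f + OR f)$ applied to the collapsed
reference frequency $f$, then spread proportionally over the gene's sites;
genotypes are drawn per allele under Hardy–Weinberg. This makes the planted
OR the exact estimand of the downstream test rather than a loose effect
label. Configurations whose planted OR would imply a case frequency above 1
are rejected at generation time.

**Why planted sites have their own frequency model.** Enriched genes draw
per-site reference frequencies uniformly in [1.5 × 10⁻³, 5 × 10⁻³] rather
than from the global Beta. The recovery guarantee this package tests —
planted OR ≥ 4 genes with collapsed panel frequency ≥ 0.01 are flagged in
≥ 90% of replicates — is a statement *conditional on the planted gene
actually being in that regime*. An unconditional Beta draw routinely breaks
the condition in two ways: the collapsed frequency lands below 0.01 (an
underpowered regime — at the 0.01 boundary the ideal test itself has only
~82% power), or a single common site (frequency ≥ 0.01) carries most of the
gene's mass and is then removed by the rarity filter, eroding the planted
signal. Drawing planted sites individually rare with a collapsed sum of
~0.012–0.04 (for the default eight sites) enforces the stated precondition;
null genes keep the untouched Beta draw.

**Mutual consistency.** The severe subset is one random subsample drawn
from its own seed stream, so the case VCF's sample labels, the SV call
set's severe carrier counts (carriers among severe samples, never exceeding
case carriers) and the clinical table's THI ≥ 58 records all name the same
individuals. Genes are tiled at fixed 100 kb offsets on one
pseudo-chromosome with 10 kb bodies, which keeps all interval arithmetic
honest without a genome build; background SVs that should *not* overlap
constrained regions are placed beyond the tiling, because a 1 Mb call
placed between tiles would drag across constrained genes.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: linkage disequilibrium and haplotype
structure, population stratification between cohort and panel, sequencing
and genotyping error, annotation error (consequence terms are drawn, not
predicted), coverage heterogeneity, and relatedness. A real analysis
inherits all of these from its upstream pipeline; the tests here establish
that the statistics and filters do what they claim under their own
assumptions.

## Clinical comparisons

Comorbidity flags are compared with a Pearson chi-squared without
continuity correction, falling back to Fisher's exact test when any
expected cell is below 5 (the fallback is recorded in the output row).
Continuous features use Welch's unequal-variance t — the source does not
state pooled vs Welch, and Welch is the safer default — with a
Shapiro–Wilk normality p recorded per group. Displayed proportions are
`round(100·count/total)` to match published "n (%)" cells. One published
comparison is a severe subset against its own superset; the package
computes such comparisons as printed but flags them `groups_overlap`,
because the chi-squared independence assumption does not hold and the
printed p-values for that table are not reproducible under any standard
2×2 construction — they are treated as formatting targets (the counts and
percentages), never as numeric test targets.

## Co-expression

`probe_correlations()` computes Pearson correlations with two-sided p
between all probe pairs of a gene across brain regions.
`coexpressed_regions()` then reduces each gene to its probes that appear in
at least one significantly correlated pair (p < 0.05 — the source states no
threshold, so the conventional one is used and exposed as an argument) and
reports regions where every listed gene has a selected probe above
threshold. The expression threshold defaults to each probe's own row
median, making "co-expressed" mean "jointly above typical level" without
assuming a calibrated intensity scale; both thresholds are arguments.

## Problem sizes used by the test suite

The suite's simulation sizes are chosen to give stable Monte-Carlo answers
at interactive runtimes: the null calibration uses one 2000-gene cohort
(one pooled test per gene, rejection rate compared against the exact
binomial 99% interval around α = 0.05); the recovery checks use 200
replicates each for the OR-4 gene and the planted recurrent deletion; the
oracle comparisons use 1000 random 2×2 tables (relative tolerance 1e-9)
and 1000 random interval configurations against per-base counting; the
round-trips use 100-record fixtures. The whole suite and the acceptance
script each complete in about two minutes on one CPU.

## Known limitations

* No kernel/dispersion tests (SKAT-style), no covariate or relatedness
  adjustment, by design — the reference-panel comparison admits none.
* Carrier-mode collapsing for SNVs approximates panel carrier counts by
  allele counts (panels publish alleles, not carriers); at rare frequencies
  the two differ negligibly, and allele mode is the default.
* The ACMG rubric is a three-rule stand-in, not the full point-based
  scheme; it is configurable precisely because it is simplified.
* VCF support covers the annotated-cohort subset the pipeline consumes
  (GT fields, per-ALT INFO annotations, multiallelic splitting) — not
  phasing, breakends, or symbolic alleles beyond what SV tables carry.
* Published gene-level odds ratios from the motivating study cannot be
  recomputed here because the underlying per-gene allele counts are not
  printed and the cohort data are access-restricted; the package instead
  verifies its statistics against oracles and planted truth, and verifies
  the published numbers that *are* recomputable (carrier frequencies and
  clinical percentages) from their printed counts.
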