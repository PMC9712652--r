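# tinburden

Rare-variant and structural-variant burden analysis for extreme-phenotype
cohorts, built for study designs where a modest case cohort (tens to a
hundred genomes) is tested against large external population reference
panels rather than matched controls. The motivating application is severe
tinnitus genetics — a discovery cohort of 97 chronic-tinnitus genomes with a
34-case severe subset (THI ≥ 58), a 147-case replication cohort, and
1000-sample population panels — but every stage is generic.

## What it computes

**Collapsing gene burden.** Coding variants are classified by consequence
(LoF = stop-gain/stop-loss/start-loss/frameshift/splice donor/acceptor;
missense; synonymous), by rarity (MAF < 0.01 in every reference panel), by
damage (CADD phred > 20) and by gene constraint (pLI ≥ 0.9, LOEUF < 0.5).
Rare qualifying alleles are summed per gene and class into a 2×2 table of
alt vs non-alt chromosomes, cases vs panel:

    OR = (a·d)/(b·c),   95% CI = exp( ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d) )

with a Pearson chi-squared statistic (1 df, no continuity correction) on the
raw cells and a Haldane–Anscombe +0.5 applied to the OR/CI cells only when a
cell is zero. A gene is *enriched* when p < α and OR > 1, and *replicated*
when enriched against at least one panel in both the discovery and the
replication cohort.

**Structural-variant prioritization and burden.** DEL/DUP calls pass a
1 kb–1 Mb size window (larger calls survive only with ≥ 99% reciprocal
overlap with a known SV), a blacklist-artifact filter (dropped when > 66% of
the call is covered by gaps/segmental duplications/V(D)J regions), a
simplified rule-based ACMG classification (classes 3–5 retained), a
constrained-region flag (pLI > 0.9 and LOEUF bin < 2) and an ultra-rare flag
(reference carrier frequency ≤ 0.001). Surviving calls are tested carrier vs
non-carrier against the reference panel with the same 2×2 construction.

**Clinical comparisons and co-expression.** Chronic (TFI ≥ 48) and severe
(THI ≥ 58) subgroup selection; comorbidity 2×2 chi-squared with Fisher
fallback; Welch t with Shapiro–Wilk checks; probe–probe Pearson correlation
and joint regional co-expression from a probes × regions expression matrix.

**Synthetic studies with known ground truth.** `simulation_config()` +
`simulate_*()` generate reference panels (Beta-distributed site
frequencies), diploid Hardy–Weinberg case cohorts with per-gene enrichment
planted on the odds-ratio scale (the planted OR is exactly the estimand of
the collapsing test), SV call sets with a planted recurrent deletion in a
constrained region, and clinical tables — so calibration, power and every
filter are testable without access-restricted data.

## Worked example

```r
library(tinburden)

cfg <- simulation_config(
  n_genes = 40, variants_per_gene = 8, seed = 2026,
  enriched_genes = tibble::tibble(gene = c("GENE0001", "GENE0002"),
                                  target_or = c(4, 3),
                                  variant_class = c("MISSENSE", "LOF")))
panel  <- simulate_reference_panel(cfg)
cohort <- simulate_case_cohort(cfg, panel)
gba <- run_gene_burden(cohort$variants, cfg$n_cases,
                       constraint = simulate_gene_constraint(cfg))
head(tidy(gba), 5)
#>   gene     variant_class case_alleles panel_alleles odds_ratio ci_low ci_high  p_value enriched
#> 1 GENE0001 MISSENSE                21            66      3.56  2.13      5.95  2.9e-07 TRUE
#> 2 GENE0002 LOF                     18            58      3.42  1.97      5.94  3.5e-06 TRUE
#> 3 GENE0007 LOF                      2             3      6.93  1.15     41.8   0.0140  TRUE
#> 4 GENE0016 MISSENSE                 1             1     10.4   0.645   166.    0.0403  TRUE
#> 5 GENE0003 MISSENSE                 0            16      0.309 0.0185    5.17  0.211   FALSE
```

Both planted genes top the ranking with estimates near their planted odds
ratios (3.56 vs 4 and 3.42 vs 3); the remaining rows are null genes whose
intervals cover 1. `glance(gba)` summarises (40 genes, 65 gene × class
tests, 4 enriched at α = 0.05) and `autoplot(gba)` draws the forest plot.

The SV carrier burden applied to a published recurrent deletion's printed
carrier counts (21/97 cases vs 17/1000 reference):

```r
sizes <- c(tiger = 97, sevtin = 34, swegen = 1000)
svs <- tibble::tibble(sv_id = "TMEM132D_del", chrom = "chr12",
                      start = 129087937L, end = 129089566L, sv_type = "DEL",
                      carriers_tiger = 21L, carriers_sevtin = 8L,
                      carriers_swegen = 17L)
tidy(sv_burden(svs, "tiger", "swegen", sizes))
#>   sv_id        case_carriers case_freq ref_freq odds_ratio  p_value
#> 1 TMEM132D_del            21     0.216    0.017       16.0 1.08e-24
```

i.e. carrier frequency 0.216 vs 0.017 and p ≪ 0.001. `run_pipeline()` chains
every stage end to end on a simulated study and writes TSV outputs plus a
manifest; `render_report()` formats the results as markdown tables in the
published style (`21 (0.216)`, `62 (64%)`, `<0.001`).

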