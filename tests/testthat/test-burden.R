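test_that("collapsing sums qualifying alleles per gene and class", {
  v <- tibble::tibble(
    chrom = "chrS", pos = 1:4, ref = "A", alt = "T",
    gene = c("GENE1", "GENE1", "GENE1", "GENE2"),
    consequence = c("stop_gained", "frameshift_variant", "missense_variant",
                    "5_prime_UTR_variant"),
    cadd = 25,
    ac_case = c(2L, 1L, 5L, 3L), an_case = 194L,
    ac_ref = c(1L, NA, 10L, 2L), an_ref = 2000L
  )
  counts <- suppressMessages(collapse_gene_counts(v, 97, "ref"))
  lof <- counts[counts$gene == "GENE1" & counts$variant_class == "LOF", ]
  expect_equal(lof$case_alleles, 3L)
  expect_equal(lof$case_allele_number, 194L)
  # absent panel site contributes 0 against the declared allele number
  expect_equal(lof$panel_alleles, 1L)
  expect_equal(lof$panel_allele_number, 2000L)
  expect_equal(lof$n_variants, 2L)
  # a gene with only OTHER-class sites emits no row
  expect_false("GENE2" %in% counts$gene)
  # damaging_only drops non-damaging missense
  v$cadd[3] <- 5
  counts2 <- suppressMessages(
    collapse_gene_counts(v, 97, "ref", damaging_only = TRUE))
  expect_false("MISSENSE" %in% counts2$variant_class)
})

test_that("chi-squared matches the independent oracle on random tables", {
  withr::local_seed(401)
  n_tab <- 1000
  tabs <- tibble::tibble(
    case_alleles = sample(0:60, n_tab, replace = TRUE),
    case_allele_number = 194L,
    panel_alleles = sample(0:200, n_tab, replace = TRUE),
    panel_allele_number = 2000L
  )
  res <- burden_test(tabs)
  oracle <- mapply(chi2_oracle, res$a, res$b, res$c, res$d)
  ok <- res$a + res$c > 0 # non-degenerate
  expect_true(all(abs(res$chi2[ok] - oracle[ok]) <=
                    1e-9 * pmax(1, oracle[ok])))
  # p-values match the 1-df upper tail of the oracle statistic
  expect_equal(res$p_value[ok], pchisq(oracle[ok], 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("odds ratio, CI and degenerate-table conventions are honoured", {
  # symmetric table: OR 1, p 1
  sym <- burden_test(tibble::tibble(
    case_alleles = 10L, case_allele_number = 100L,
    panel_alleles = 10L, panel_allele_number = 100L))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$chi2, 0)

  # Haldane-Anscombe correction engages only when a cell is zero
  zero <- burden_test(tibble::tibble(
    case_alleles = 5L, case_allele_number = 100L,
    panel_alleles = 0L, panel_allele_number = 1000L))
  expect_equal(zero$odds_ratio, (5.5 / 95.5) / (0.5 / 1000.5))
  expect_true(zero$ci_low <= zero$odds_ratio & zero$odds_ratio <= zero$ci_high)
  # ... and the chi-squared still uses the raw cells
  expect_equal(zero$chi2, chi2_oracle(5, 95, 0, 1000))

  # both-empty margin: p = 1, OR missing
  degen <- burden_test(tibble::tibble(
    case_alleles = 0L, case_allele_number = 194L,
    panel_alleles = 0L, panel_allele_number = 2000L))
  expect_equal(degen$p_value, 1)
  expect_true(is.na(degen$odds_ratio))
  expect_false(degen$enriched)

  expect_error(burden_test(tibble::tibble(
    case_alleles = 0L, case_allele_number = 0L,
    panel_alleles = 1L, panel_allele_number = 10L)),
    class = "tinburden_validation_error")
})

test_that("odds ratio is strictly monotone in case alleles", {
  ors <- vapply(1:20, function(a) {
    burden_test(tibble::tibble(
      case_alleles = a, case_allele_number = 194L,
      panel_alleles = 40L, panel_allele_number = 2000L))$odds_ratio
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("Fisher option agrees with chi-squared in rank order on solid tables", {
  withr::local_seed(402)
  tabs <- tibble::tibble(
    case_alleles = sample(5:80, 200, replace = TRUE),
    case_allele_number = 194L,
    panel_alleles = sample(5:150, 200, replace = TRUE),
    panel_allele_number = 2000L
  )
  p_chi <- burden_test(tabs)$p_value
  p_fis <- burden_test(tabs, method = "fisher")$p_value
  expect_gte(cor(p_chi, p_fis, method = "spearman"), 0.99)
})

test_that("run_gene_burden orders results and handles empty input", {
  cfg <- planted_config(seed = 77)
  cohort <- simulate_case_cohort(cfg, simulate_reference_panel(cfg))
  res <- suppressMessages(
    run_gene_burden(cohort$variants, cfg$n_cases,
                    constraint = simulate_gene_constraint(cfg)))
  tb <- tidy(res)
  expect_true(!is.unsorted(tb$p_value))
  expect_true(all(c("intolerant_pli", "intolerant_loeuf") %in% names(tb)))
  # planted gene is constrained by construction
  expect_true(all(tb$intolerant_pli[tb$gene == "GENE0001"]))
  g <- glance(res)
  expect_equal(g$alpha, 0.05)
  expect_equal(g$n_tests, nrow(tb))

  empty <- run_gene_burden(cohort$variants[0, ], cfg$n_cases,
                           panels = "panel1")
  expect_equal(nrow(tidy(empty)), 0)

  adj <- suppressMessages(
    run_gene_burden(cohort$variants, cfg$n_cases, adjust = "BH"))
  expect_true("p_adjusted" %in% names(adj))
  expect_true(all(adj$p_adjusted >= adj$p_value))
})

test_that("replication requires enrichment in both cohorts, any panel", {
  mk <- function(rows) {
    structure(rows, class = c("gba", class(tibble::tibble())), alpha = 0.05)
  }
  disc <- mk(tibble::tibble(
    gene = c("G1", "G2", "G3"), variant_class = "MISSENSE",
    panel = c("A", "A", "B"), enriched = c(TRUE, TRUE, TRUE)))
  repl <- mk(tibble::tibble(
    gene = c("G1", "G3", "G9"), variant_class = "MISSENSE",
    panel = c("B", "B", "A"), enriched = c(TRUE, FALSE, TRUE)))
  out <- replicate_burden(disc, repl)
  # G1: discovery panel A, replication panel B -> replicated
  expect_equal(out$gene, "G1")
  expect_equal(out$discovery_panels, "A")
  expect_equal(out$replication_panels, "B")
  # disjoint gene sets give an empty table
  expect_equal(nrow(replicate_burden(disc, mk(tibble::tibble(
    gene = "GX", variant_class = "LOF", panel = "A", enriched = TRUE)))), 0)
})

test_that("multi-hit carriers are counted by site, not allele", {
  gt1 <- c(S1 = 1L, S2 = 0L, S3 = 2L)
  gt2 <- c(S1 = 1L, S2 = 0L, S3 = 0L)
  v <- tibble::tibble(
    chrom = "chrS", pos = c(1L, 11L), ref = "A", alt = "T",
    gene = "GENE1", consequence = "stop_gained", cadd = 30,
    ac_case = c(3L, 1L), an_case = 6L,
    gt = list(gt1, gt2)
  )
  hits <- find_multihit_carriers(v, "GENE1")
  # S1 carries both sites; S3 is homozygous at one site only
  expect_equal(hits$subject_id, "S1")
  expect_equal(hits$n_sites, 2L)
  expect_equal(nrow(find_multihit_carriers(v, character(0))), 0)
  v_nogt <- v[, setdiff(names(v), "gt")]
  expect_error(find_multihit_carriers(v_nogt, "GENE1"),
               class = "tinburden_capability_error")
})
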