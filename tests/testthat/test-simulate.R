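test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(n_severe = 200, n_cases = 97),
               class = "tinburden_config_error")
  expect_error(simulation_config(n_cases = 0), class = "tinburden_config_error")
  expect_error(simulation_config(maf_distribution = c(-1, 50)),
               class = "tinburden_config_error")
  expect_error(
    simulation_config(enriched_genes = tibble::tibble(
      gene = "GENE0001", target_or = -2, variant_class = "LOF")),
    class = "tinburden_config_error")
  expect_error(simulation_config(sv_spec = list(length_range = c(10, 5))),
               class = "tinburden_config_error")
  expect_error(
    simulation_config(clinical_probs = tibble::tibble(
      feature = "hyperacusis", p_severe = 1.2, p_nonsevere = 0.5)),
    class = "tinburden_config_error")
})

test_that("reference panel has forced allele numbers and mostly rare variants", {
  cfg <- simulation_config(n_genes = 100, variants_per_gene = 20, seed = 1,
                           n_reference = c(ref = 1000))
  panel <- simulate_reference_panel(cfg)
  expect_equal(nrow(panel), 2000)
  expect_true(all(panel$an == 2000))
  # Beta(0.2, 50) places ~88% of its mass below 0.01; the realized panel
  # frequencies should stay clearly in the rare-variant regime
  expect_gt(mean(panel$freq < 0.01), 0.8)
})

test_that("generators are deterministic and streams are independent", {
  cfg <- small_config(seed = 99)
  expect_identical(simulate_reference_panel(cfg), simulate_reference_panel(cfg))
  p <- simulate_reference_panel(cfg)
  expect_identical(simulate_case_cohort(cfg, p), simulate_case_cohort(cfg, p))
  expect_identical(simulate_sv_callset(cfg), simulate_sv_callset(cfg))
  expect_identical(simulate_clinical_table(cfg), simulate_clinical_table(cfg))
  # different seed, different data
  cfg2 <- small_config(seed = 100)
  expect_false(identical(simulate_reference_panel(cfg2), p))
})

test_that("case cohort has the declared samples and a labelled severe subset", {
  cfg <- small_config()
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_case_cohort(cfg, panel)
  expect_equal(nrow(cohort$samples), 97)
  expect_equal(sum(cohort$samples$severe), 34)
  expect_equal(length(cohort$variants$gt[[1]]), 97)
  expect_true(all(cohort$variants$ac_case <= cohort$variants$an_case))
  expect_equal(unique(cohort$variants$an_case), 194)
  # ground truth covers every gene exactly once
  expect_setequal(cohort$truth$gene, sprintf("GENE%04d", 1:cfg$n_genes))
  expect_equal(anyDuplicated(cohort$truth$gene), 0)
  # replication cohort is its own draw with its own size
  repl <- simulate_case_cohort(cfg, panel, "replication")
  expect_equal(nrow(repl$samples), 147)
  expect_false(identical(repl$variants$ac_case, cohort$variants$ac_case))
})

test_that("null genes track the panel frequency and planted genes the target OR", {
  # pooled over replicates, collapsed case frequency of a target_or = 1 gene
  # matches the panel's collapsed frequency, and a target_or = 4 gene's
  # estimated OR is within 25% of 4
  n_rep <- 300
  or_hat <- numeric(n_rep)
  ratio_num <- 0
  ratio_den <- 0
  for (r in seq_len(n_rep)) {
    cfg <- planted_config(seed = 1000 + r, target_or = 4)
    panel <- simulate_reference_panel(cfg)
    cohort <- simulate_case_cohort(cfg, panel)
    v <- cohort$variants
    planted <- v[v$gene == "GENE0001", ]
    null_g <- v[v$gene == "GENE0002", ]
    a <- sum(planted$ac_case); an <- planted$an_case[1]
    c_ <- sum(planted$ac_panel1); cn <- planted$an_panel1[1]
    ha <- 0.5 * (a == 0 || c_ == 0)
    or_hat[r] <- ((a + ha) / (an - a + ha)) / ((c_ + ha) / (cn - c_ + ha))
    ratio_num <- ratio_num + sum(null_g$ac_case) / null_g$an_case[1]
    ratio_den <- ratio_den + sum(null_g$ac_panel1) / null_g$an_panel1[1]
  }
  expect_lt(abs(mean(or_hat) - 4) / 4, 0.25)
  expect_lt(abs(ratio_num / ratio_den - 1), 0.15)
})

test_that("impossible planted enrichment is rejected", {
  # enough sites that the gene-level collapsed reference frequency exceeds 1
  cfg <- simulation_config(
    n_genes = 2, variants_per_gene = 500, seed = 9,
    enriched_genes = tibble::tibble(gene = "GENE0001", target_or = 4,
                                    variant_class = "MISSENSE"))
  expect_error(simulate_case_cohort(cfg, simulate_reference_panel(cfg)),
               class = "tinburden_config_error")
})

test_that("SV call set respects lengths, carrier bounds and constrained placement", {
  cfg <- small_config(sv_spec = list(length_range = c(1000, 1000000)))
  svset <- simulate_sv_callset(cfg)
  lens <- svset$svs$end - svset$svs$start
  expect_true(all(lens >= 1000 & lens <= 1000000))
  expect_true(all(svset$svs$carriers_cases <= 97))
  expect_true(all(svset$svs$carriers_severe <= svset$svs$carriers_cases))
  expect_true(all(svset$svs$carriers_reference <= 1000))
  expect_equal(nrow(svset$truth), nrow(svset$svs))
  # planted deletion overlaps a constrained gene
  con <- sv_constrained_overlap(svset$svs, svset$gene_intervals,
                                svset$constraint)
  expect_true(con$constrained[1])

  # with constrained overlap disabled nothing lands in constrained regions
  cfg0 <- small_config(sv_spec = list(constrained_overlap_fraction = 0))
  svset0 <- simulate_sv_callset(cfg0)
  con0 <- sv_constrained_overlap(svset0$svs, svset0$gene_intervals,
                                 svset0$constraint)
  expect_equal(sum(con0$constrained), 0)
})

test_that("planted recurrent deletion is detected by the carrier burden test", {
  # deletion planted at case carrier frequency 0.216 vs reference 0.017:
  # the chi-squared burden should reject at alpha = 0.001 essentially always
  hits <- 0
  for (r in 1:50) {
    svset <- simulate_sv_callset(small_config(seed = 2000 + r))
    b <- sv_burden(svset$svs, "cases", "reference", svset$cohort_sizes)
    row <- b[b$sv_id == "SV001", ]
    hits <- hits + (row$p_value < 0.001)
  }
  expect_gte(hits, 48)
})

test_that("clinical table matches the configured severity model", {
  cfg <- small_config()
  clin <- simulate_clinical_table(cfg)
  expect_equal(nrow(clin), 97)
  expect_true(all(clin$thi[clin$severe] >= 58))
  expect_true(all(clin$thi[!clin$severe] < 58))
  expect_true(all(clin$tfi >= 48))
  expect_true(all(clin$duration_category %in%
                    c("6m-3y", "3-10y", "10-20y", ">20y", "missing")))

  # severe flags agree with the cohort's severe subsample
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_case_cohort(cfg, panel)
  expect_identical(clin$severe,
                   cohort$samples$severe[match(clin$subject_id,
                                               cohort$samples$sample_id)])

  # zero probabilities silence every flag
  cfg0 <- small_config(clinical_probs = tibble::tibble(
    feature = c("hearing_loss", "hyperacusis"), p_severe = 0, p_nonsevere = 0))
  clin0 <- simulate_clinical_table(cfg0)
  expect_false(any(clin0$hearing_loss) || any(clin0$hyperacusis))
})

test_that("severe comorbidity rates land in the binomial envelope", {
  # pooled severe hyperacusis proportion over replicates, planted at 0.94,
  # stays inside the exact binomial 99% interval
  n_rep <- 200
  count <- 0
  for (r in seq_len(n_rep)) {
    clin <- simulate_clinical_table(small_config(seed = 3000 + r))
    count <- count + sum(clin$hyperacusis[clin$severe])
  }
  n_total <- n_rep * 34
  ci <- binom99(n_total, 0.94)
  expect_gte(count / n_total, ci[1])
  expect_lte(count / n_total, ci[2])
})
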