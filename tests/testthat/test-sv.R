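sv_row <- function(start, end, type = "DEL", chrom = "chrS", id = "SV1") {
  tibble::tibble(sv_id = id, chrom = chrom, start = start, end = end,
                 sv_type = type)
}

test_that("size window is inclusive and oversized calls need known support", {
  svs <- dplyr::bind_rows(
    sv_row(0L, 999L, id = "small"),
    sv_row(0L, 1000L, id = "min"),
    sv_row(0L, 1000000L, id = "max"),
    sv_row(0L, 2000000L, id = "big")
  )
  parts <- sv_filter_size(svs)
  expect_setequal(parts$kept$sv_id, c("min", "max"))
  expect_equal(parts$oversized$sv_id, "big")
  # 2 Mb call with no known match is dropped by the rescue path
  rescued <- sv_filter_known(parts$oversized,
                             sv_row(5e6L, 7e6L, id = "far"), 0.99)
  expect_equal(nrow(rescued), 0)
  # ... but survives with a near-identical known call
  rescued2 <- sv_filter_known(parts$oversized, sv_row(0L, 1999000L), 0.99)
  expect_equal(rescued2$sv_id, "big")
})

test_that("covered_fraction matches hand arithmetic and ignores fragmentation", {
  regions <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(chrom = "chrS", start = m[, 1], end = m[, 2])
  }
  expect_equal(covered_fraction(sv_row(100L, 200L), regions(100, 200)), 1)
  expect_equal(covered_fraction(sv_row(0L, 100L), regions(0, 30, 30, 60)), 0.6)
  expect_equal(covered_fraction(sv_row(0L, 100L), regions(200, 300)), 0)
  # overlapping regions are not double-counted
  expect_equal(covered_fraction(sv_row(0L, 100L), regions(0, 50, 20, 60)), 0.6)
  # fragmenting a region leaves the value unchanged, in any row order
  whole <- covered_fraction(sv_row(1000L, 2000L), regions(1200, 1900))
  frag <- regions(1500, 1900, 1200, 1350, 1350, 1500)
  expect_equal(covered_fraction(sv_row(1000L, 2000L), frag), whole)
})

test_that("interval overlaps match brute-force per-base counting", {
  withr::local_seed(403)
  for (rep in 1:150) {
    s <- sample(0:200, 1); e <- s + sample(1:100, 1)
    n_reg <- sample(1:4, 1)
    rs <- sample(0:250, n_reg, replace = TRUE)
    re <- rs + sample(1:80, n_reg, replace = TRUE)
    regions <- tibble::tibble(chrom = "chrS", start = rs, end = re)
    expect_equal(covered_fraction(sv_row(s, e), regions),
                 covered_fraction_bruteforce(s, e, regions),
                 tolerance = 1e-12)
    b_s <- sample(0:200, 1); b_e <- b_s + sample(1:100, 1)
    expect_equal(reciprocal_overlap(s, e, b_s, b_e),
                 reciprocal_overlap_bruteforce(s, e, b_s, b_e),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(reciprocal_overlap(s, e, b_s, b_e),
                 reciprocal_overlap(b_s, b_e, s, e))
  }
})

test_that("blacklist filtering drops calls covered strictly above 66%", {
  bl <- tibble::tibble(chrom = "chrS", start = 0L, end = 661L)
  sv66 <- sv_row(0L, 1000L, id = "at66")   # covered exactly 0.661 -> dropped
  expect_equal(nrow(sv_filter_artifacts(sv66, bl)), 0)
  bl$end <- 660L                            # exactly 0.66 -> kept
  expect_equal(sv_filter_artifacts(sv66, bl)$sv_id, "at66")
  # empty blacklist keeps everything
  expect_equal(nrow(sv_filter_artifacts(sv66, bl[0, ])), 1)
})

test_that("known-SV concordance is reciprocal, type-matched and inclusive at 99%", {
  sv <- sv_row(0L, 1000L)
  expect_equal(reciprocal_overlap(0, 1000, 0, 990), 0.99)
  expect_equal(sv_filter_known(sv, sv_row(0L, 990L))$sv_id, "SV1")
  expect_equal(nrow(sv_filter_known(sv, sv_row(0L, 989L))), 0)
  # same interval, wrong type
  expect_equal(nrow(sv_filter_known(sv, sv_row(0L, 1000L, type = "DUP"))), 0)
})

test_that("ACMG rubric is deterministic with benign overlap outranking", {
  svs <- tibble::tibble(
    sv_id = c("benign", "patho", "vus", "none"),
    chrom = "chrS", start = 0L, end = 100L, sv_type = "DEL",
    benign_overlap = c(TRUE, FALSE, FALSE, FALSE),
    dosage_sensitive_loss = c(FALSE, TRUE, FALSE, FALSE),
    constrained_gene_overlap = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- sv_classify_acmg(svs)
  expect_equal(out$acmg_class, c(2L, 4L, 3L, 2L))
  expect_identical(sv_classify_acmg(svs)$acmg_class, out$acmg_class)
  expect_equal(retain_reportable(out)$sv_id, c("patho", "vus"))
  bad_rules <- tibble::tibble(evidence = "no_such_flag", class = 3L)
  expect_error(sv_classify_acmg(svs, bad_rules), "no_such_flag",
               class = "tinburden_config_error")
})

test_that("constrained overlap needs pLI > 0.9 and LOEUF bin < 2, both strict", {
  gi <- tibble::tibble(gene = c("GA", "GB", "GC"), chrom = "chrS",
                       start = c(0L, 200L, 400L), end = c(100L, 300L, 500L))
  constraint <- tibble::tibble(
    gene = c("GA", "GB", "GC"),
    pli = c(0.95, 0.95, 0.9),
    loeuf = c(0.3, 0.3, 0.3),
    loeuf_bin = c(1L, 2L, 1L)
  )
  out <- sv_constrained_overlap(
    dplyr::bind_rows(sv_row(50L, 150L, id = "hitA"),
                     sv_row(220L, 280L, id = "hitB"),
                     sv_row(410L, 490L, id = "hitC"),
                     sv_row(600L, 700L, id = "none")),
    gi, constraint)
  # GA qualifies; GB fails bin (= 2); GC fails pli (= 0.9); no overlap fails
  expect_equal(out$constrained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$constrained_genes, c("GA", "", "", ""))
})

test_that("ultra-rare flag is inclusive at the panel resolution", {
  sizes <- c(cases = 97, reference = 1000)
  svs <- tibble::tibble(sv_id = c("a", "b", "c"), chrom = "chrS",
                        start = 0L, end = 100L, sv_type = "DEL",
                        carriers_reference = c(1L, 17L, NA))
  out <- sv_flag_ultra_rare(svs, "reference", sizes)
  expect_equal(out$ultra_rare, c(TRUE, FALSE, TRUE))
})

test_that("SV carrier burden reproduces published-style rows and conventions", {
  sizes <- c(cases = 97, severe = 34, reference = 1000)
  svs <- tibble::tibble(
    sv_id = c("recurrent_del", "quiet"),
    chrom = "chrS", start = c(0L, 5000L), end = c(1650L, 7000L),
    sv_type = "DEL",
    carriers_cases = c(21L, 0L), carriers_severe = c(8L, 0L),
    carriers_reference = c(17L, 0L)
  )
  res <- sv_burden(svs, "cases", "reference", sizes)
  top <- res[res$sv_id == "recurrent_del", ]
  expect_equal(top$case_freq, 0.216)
  expect_equal(top$ref_freq, 0.017)
  expect_lt(top$p_value, 0.001)
  # degenerate all-zero row: p = 1, OR missing
  quiet <- res[res$sv_id == "quiet", ]
  expect_equal(quiet$p_value, 1)
  expect_true(is.na(quiet$odds_ratio))
  # severe subset frequency as printed
  res_sev <- sv_burden(svs, "severe", "reference", sizes)
  expect_equal(res_sev$case_freq[res_sev$sv_id == "recurrent_del"], 0.235)

  expect_error(sv_burden(svs, "cases", "missing_cohort", sizes),
               class = "tinburden_validation_error")

  # grouped mode clusters by type and constraint
  svs$constrained <- c(TRUE, FALSE)
  grouped <- sv_burden(svs, "cases", "reference", sizes,
                       grouping = "type_constraint")
  expect_setequal(grouped$sv_id, c("DEL_constrained", "DEL_other"))
})

test_that("prioritization stages compose to the same set as joint filtering", {
  svset <- simulate_sv_callset(small_config(seed = 404))
  svs <- svset$svs
  kept <- sv_prioritize(svs, svset$regions$blacklist, svset$known,
                        svset$gene_intervals, svset$constraint,
                        "reference", svset$cohort_sizes)
  # recompute each predicate independently and intersect
  len <- svs$end - svs$start
  in_window <- len >= 1000 & len <= 1000000
  bl_frac <- covered_fraction(svs, svset$regions$blacklist)
  known_ok <- rep(FALSE, nrow(svs))
  for (i in seq_len(nrow(svs))) {
    k <- svset$known[svset$known$sv_type == svs$sv_type[i], ]
    if (nrow(k)) {
      known_ok[i] <- max(reciprocal_overlap(svs$start[i], svs$end[i],
                                            k$start, k$end)) >= 0.99
    }
  }
  con <- sv_constrained_overlap(svs, svset$gene_intervals, svset$constraint)
  reportable <- !svs$benign_overlap & con$constrained
  manual <- svs$sv_id[(in_window | (len > 1000000 & known_ok)) &
                        bl_frac <= 0.66 & known_ok & reportable]
  expect_setequal(kept$sv_id, manual)
})
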