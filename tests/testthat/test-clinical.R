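clin_fixture <- function() simulate_clinical_table(small_config(seed = 31))

test_that("chronic and severe selection use inclusive cutoffs", {
  clin <- clin_fixture()
  clin$tfi[1] <- 48
  clin$tfi[2] <- 47.9
  chronic <- select_chronic(clin)
  expect_true(clin$subject_id[1] %in% chronic$subject_id)
  expect_false(clin$subject_id[2] %in% chronic$subject_id)
  expect_equal(nrow(select_chronic(clin[0, ])), 0)

  clin$thi[1] <- 58
  clin$thi[2] <- 57
  severe <- select_severe(clin)
  expect_true(clin$subject_id[1] %in% severe$subject_id)
  expect_false(clin$subject_id[2] %in% severe$subject_id)
  all_severe <- clin[clin$thi >= 58, ]
  expect_identical(select_severe(all_severe), all_severe)
})

test_that("categorical comparison reports whole-percent proportions", {
  # 32/34 displays as 94%, 62/97 as 64%
  a <- tibble::tibble(subject_id = sprintf("A%02d", 1:97),
                      hyperacusis = rep(c(TRUE, FALSE), c(67, 30)),
                      hearing_loss = rep(c(TRUE, FALSE), c(62, 35)))
  b <- tibble::tibble(subject_id = sprintf("B%02d", 1:34),
                      hyperacusis = rep(c(TRUE, FALSE), c(32, 2)),
                      hearing_loss = rep(c(TRUE, FALSE), c(27, 7)))
  cmp <- compare_categorical(a, b, c("hyperacusis", "hearing_loss"))
  expect_equal(cmp$pct_b[cmp$feature == "hyperacusis"], 94L)
  expect_equal(cmp$pct_a[cmp$feature == "hearing_loss"], 64L)
  expect_equal(cmp$pct_a, as.integer(round(100 * cmp$count_a / cmp$total_a)))
  expect_false(any(cmp$groups_overlap))

  # identical groups: association vanishes
  same <- compare_categorical(a, dplyr::mutate(a, subject_id = paste0("C", subject_id)),
                              "hyperacusis")
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  # subset-vs-superset comparisons are flagged non-independent
  cmp2 <- suppressMessages(compare_categorical(a, a[1:30, ], "hyperacusis"))
  expect_true(all(cmp2$groups_overlap))

  expect_error(compare_categorical(a[0, ], b),
               class = "tinburden_validation_error")
})

test_that("sparse tables fall back to Fisher and record it", {
  a <- tibble::tibble(flag = rep(c(TRUE, FALSE), c(2, 28)))
  b <- tibble::tibble(flag = rep(c(TRUE, FALSE), c(1, 9)))
  cmp <- compare_categorical(a, b, "flag")
  expect_equal(cmp$test, "fisher")
  expect_true(is.na(cmp$statistic))
  big <- tibble::tibble(flag = rep(c(TRUE, FALSE), c(40, 60)))
  expect_equal(compare_categorical(big, big, "flag")$test, "chi-squared")
})

test_that("categorical comparison is symmetric up to direction", {
  a <- tibble::tibble(flag = rep(c(TRUE, FALSE), c(40, 57)))
  b <- tibble::tibble(flag = rep(c(TRUE, FALSE), c(25, 9)))
  ab <- compare_categorical(a, b, "flag")
  ba <- compare_categorical(b, a, "flag")
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
})

test_that("continuous comparison uses Welch's t with normality checks", {
  a <- tibble::tibble(age = c(40, 45, 50, 55, 60))
  cmp <- compare_continuous(a, a, "age")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$test, "welch_t")
  expect_true(all(c("shapiro_p_a", "shapiro_p_b") %in% names(cmp)))

  expect_error(compare_continuous(a[1:2, ], a, "age"),
               class = "tinburden_validation_error")
  const <- tibble::tibble(age = rep(50, 10))
  expect_error(compare_continuous(const, a, "age"),
               class = "tinburden_validation_error")
})

test_that("the t test is calibrated under the null", {
  withr::local_seed(405)
  n_rep <- 500
  rej <- 0
  for (r in seq_len(n_rep)) {
    a <- tibble::tibble(x = rnorm(20, 50, 10))
    b <- tibble::tibble(x = rnorm(25, 50, 10))
    rej <- rej + (compare_continuous(a, b, "x")$p_value < 0.05)
  }
  ci <- binom99(n_rep, 0.05)
  expect_gte(rej / n_rep, ci[1])
  expect_lte(rej / n_rep, ci[2])
})
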