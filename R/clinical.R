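# Phenotype subgroup selection and clinical feature comparisons for the
# extreme-phenotype design: chronic inclusion by Tinnitus Functional Index
# (TFI >= 48, "tinnitus is a big problem"), severe subset by Tinnitus
# Handicap Inventory (THI >= 58).

#' Select chronic cases
#'
#' Keeps records with TFI at or above the cutoff (default 48) and a tinnitus
#' duration beyond six months. Every category of the duration vocabulary
#' starts at six months, so records are dropped on duration only if their
#' category is outside the vocabulary; `missing` duration is retained, as
#' case series typically include subjects with unrecorded onset.
#'
#' @param records Clinical tibble.
#' @param tfi_min TFI inclusion cutoff (inclusive).
#' @return The chronic subset.
#' @export
select_chronic <- function(records, tfi_min = 48) {
  records[records$tfi >= tfi_min &
            records$duration_category %in% .DURATION_LEVELS, , drop = FALSE]
}

#' Select the severe subset
#'
#' Keeps records with THI at or above the cutoff (default 58, inclusive).
#'
#' @param records Clinical tibble.
#' @param thi_min THI severity cutoff.
#' @return The severe subset.
#' @export
select_severe <- function(records, thi_min = 58) {
  records[records$thi >= thi_min, , drop = FALSE]
}

#' Compare a binary clinical feature between two groups
#'
#' Builds the 2x2 table of flag counts and tests it with a Pearson
#' chi-squared without continuity correction, falling back to Fisher's exact
#' test whenever an expected cell is below 5 (the fallback is recorded in the
#' `test` column). Displayed proportions are rounded to whole percent. When
#' the two groups share subject ids (a subset compared against its superset)
#' the comparison is still computed but flagged non-independent.
#'
#' @param group_a,group_b Clinical tibbles.
#' @param features Logical feature columns to compare; default the five
#'   comorbidity flags present in both groups.
#' @return Tibble, one row per feature: counts, totals, percentages, test
#'   name, statistic, p-value, `groups_overlap`.
#' @export
compare_categorical <- function(group_a, group_b, features = NULL) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    abort_validation("Both groups must be non-empty.")
  }
  features <- features %||%
    intersect(.COMORBIDITIES, intersect(names(group_a), names(group_b)))
  overlap <- "subject_id" %in% names(group_a) &&
    "subject_id" %in% names(group_b) &&
    length(intersect(group_a$subject_id, group_b$subject_id)) > 0
  if (overlap) {
    notify("Groups share subjects; the comparison is not independent.")
  }
  purrr::map_dfr(features, function(f) {
    xa <- group_a[[f]]
    xb <- group_b[[f]]
    if (!is.logical(xa) || !is.logical(xb)) {
      abort_validation(sprintf("Feature `%s` must be logical in both groups.", f))
    }
    ca <- sum(xa, na.rm = TRUE); na_ <- sum(!is.na(xa))
    cb <- sum(xb, na.rm = TRUE); nb <- sum(!is.na(xb))
    m <- matrix(c(ca, na_ - ca, cb, nb - cb), nrow = 2)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5)) {
      ft <- fisher.test(m)
      test <- "fisher"; statistic <- NA_real_; p <- ft$p.value
    } else {
      ct <- chisq.test(m, correct = FALSE)
      test <- "chi-squared"; statistic <- unname(ct$statistic); p <- ct$p.value
    }
    tibble::tibble(
      feature = f,
      count_a = ca, total_a = na_,
      pct_a = as.integer(round(100 * ca / na_)),
      count_b = cb, total_b = nb,
      pct_b = as.integer(round(100 * cb / nb)),
      test = test, statistic = statistic, p_value = p,
      groups_overlap = overlap
    )
  })
}

#' Compare a continuous clinical feature between two groups
#'
#' Welch two-sample t test (unequal variances), with a Shapiro-Wilk
#' normality check recorded per group. Groups need at least three
#' observations and non-zero variance.
#'
#' @param group_a,group_b Clinical tibbles.
#' @param feature Numeric column name.
#' @return One-row tibble: group means and SDs, Shapiro-Wilk p per group,
#'   Welch t statistic and p-value.
#' @export
compare_continuous <- function(group_a, group_b, feature) {
  xa <- group_a[[feature]]
  xb <- group_b[[feature]]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 3 || length(xb) < 3) {
    abort_validation(sprintf("Feature `%s` needs >= 3 observations per group.",
                             feature))
  }
  if (var(xa) == 0 || var(xb) == 0) {
    abort_validation(sprintf(
      "Feature `%s` is constant within a group; the t test is undefined.",
      feature))
  }
  tt <- t.test(xa, xb, var.equal = FALSE)
  tibble::tibble(
    feature = feature,
    mean_a = mean(xa), sd_a = sd(xa), n_a = length(xa),
    mean_b = mean(xb), sd_b = sd(xb), n_b = length(xb),
    shapiro_p_a = shapiro.test(xa)$p.value,
    shapiro_p_b = shapiro.test(xb)$p.value,
    test = "welch_t",
    statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}
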