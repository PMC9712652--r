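# Consequence / rarity / damage / constraint classification of coding
# variants. Boundary semantics, taken literally from the filtering scheme the
# package implements: rare <=> MAF < 0.01 in every panel; damaging <=> CADD
# phred > 20 (strict); LoF-intolerant <=> pLI >= 0.9; high-constraint <=>
# LOEUF < 0.5.

the_vocab_cache <- new.env(parent = emptyenv())

#' The consequence vocabulary table
#'
#' The controlled vocabulary mapping annotation consequence terms to the four
#' collapsing classes. Shipped as a versioned TSV under `extdata`; LOF covers
#' exactly stop-gain, stop-loss, start-loss, frameshift and splice
#' donor/acceptor.
#'
#' @param path Optional path to an alternative vocabulary TSV with columns
#'   `term` and `class`.
#' @return Tibble with columns `term`, `class`.
#' @export
consequence_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the_vocab_cache$default)) {
      path <- system.file("extdata", "consequence_vocabulary.tsv",
                          package = "tinburden", mustWork = TRUE)
      the_vocab_cache$default <- readr::read_tsv(path, col_types = "cc")
    }
    return(the_vocab_cache$default)
  }
  vocab <- readr::read_tsv(path, col_types = "cc")
  if (!all(c("term", "class") %in% names(vocab))) {
    abort_format("Vocabulary TSV needs columns `term` and `class`.")
  }
  vocab
}

#' Classify consequence terms into collapsing classes
#'
#' Total, case-insensitive mapping from annotation consequence terms to
#' `LOF`, `MISSENSE`, `SYNONYMOUS` or `OTHER`. Terms outside the vocabulary
#' map to `OTHER` with a notice.
#'
#' @param terms Character vector of consequence terms.
#' @param vocabulary Vocabulary tibble, defaults to the shipped table.
#' @return Factor with levels LOF, MISSENSE, SYNONYMOUS, OTHER.
#' @export
#' @examples
#' classify_consequence(c("stop_gained", "missense_variant", "intergenic_variant"))
classify_consequence <- function(terms, vocabulary = consequence_vocabulary()) {
  if (any(!nzchar(terms) | is.na(terms))) {
    abort_validation("Consequence terms must be non-empty.")
  }
  cls <- vocabulary$class[match(tolower(terms), tolower(vocabulary$term))]
  unknown <- unique(terms[is.na(cls)])
  if (length(unknown) > 0) {
    notify(sprintf("%d consequence term(s) outside the vocabulary mapped to OTHER: %s",
                   length(unknown),
                   paste(head(unknown, 5), collapse = ", ")))
  }
  cls[is.na(cls)] <- "OTHER"
  factor(cls, levels = c("LOF", "MISSENSE", "SYNONYMOUS", "OTHER"))
}

#' Is a variant damaging by CADD phred score?
#'
#' Strictly greater than the threshold (default 20); missing scores are
#' conservatively non-damaging.
#'
#' @param cadd_phred Numeric vector (NA allowed).
#' @param threshold Score threshold, default 20.
#' @return Logical vector.
#' @export
is_damaging <- function(cadd_phred, threshold = 20) {
  !is.na(cadd_phred) & cadd_phred > threshold
}

#' Is a variant rare in every reference panel?
#'
#' A variant is rare iff its allele frequency is strictly below the threshold
#' in every supplied panel. Variants absent from a panel of declared size
#' (missing allele count) are treated as frequency 0 in that panel.
#'
#' @param variants Variant tibble with `ac_<panel>` / `an_<panel>` columns.
#' @param panels Panel names to consider; default all panels present.
#' @param threshold MAF threshold, default 0.01 (frequencies at or above it
#'   are the common side).
#' @return Logical vector, one element per variant.
#' @export
is_rare <- function(variants, panels = NULL, threshold = 0.01) {
  panels <- panels %||% panel_names(variants)
  if (length(panels) == 0) {
    abort_config("No reference panels supplied (no `ac_<panel>` columns found).")
  }
  rare <- rep(TRUE, nrow(variants))
  for (p in panels) {
    ac <- variants[[paste0("ac_", p)]]
    an <- variants[[paste0("an_", p)]]
    if (is.null(ac) || is.null(an)) {
      abort_config(sprintf("Panel `%s` columns ac_%s/an_%s not found.", p, p, p))
    }
    freq <- ifelse(is.na(ac) | is.na(an) | an == 0, 0, ac / an)
    rare <- rare & freq < threshold
  }
  rare
}

# Panel names inferred from paired ac_<name>/an_<name> columns; the case
# cohort's own ac_case/an_case columns are not a panel.
panel_names <- function(variants) {
  ac <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  an <- sub("^an_", "", grep("^an_", names(variants), value = TRUE))
  setdiff(intersect(ac, an), "case")
}

#' Gene-level constraint flags
#'
#' For each gene, `intolerant_pli` is pLI >= 0.9 and `intolerant_loeuf` is
#' LOEUF < 0.5. Genes absent from the constraint table get both flags FALSE
#' with a notice.
#'
#' @param genes Character vector of gene symbols.
#' @param constraint Constraint tibble (`gene`, `pli`, `loeuf`, ...).
#' @return Tibble with columns `gene`, `intolerant_pli`, `intolerant_loeuf`.
#' @export
constraint_flags <- function(genes, constraint) {
  idx <- match(genes, constraint$gene)
  if (anyNA(idx)) {
    miss <- unique(genes[is.na(idx)])
    notify(sprintf("%d gene(s) absent from the constraint table (flags FALSE): %s",
                   length(miss), paste(head(miss, 5), collapse = ", ")))
  }
  tibble::tibble(
    gene = genes,
    intolerant_pli = !is.na(idx) & constraint$pli[idx] >= 0.9,
    intolerant_loeuf = !is.na(idx) & constraint$loeuf[idx] < 0.5
  )
}

#' Minimum observable allele frequency of a cohort
#'
#' The resolution floor 1/(2N) for a diploid cohort of N samples: one allele
#' among 2N chromosomes. Used to annotate variants at the cohort's frequency
#' resolution, not to drop them.
#'
#' @param n_samples Cohort size (>= 1).
#' @return `1 / (2 * n_samples)`.
#' @export
#' @examples
#' cohort_maf_floor(97) # 1/194
cohort_maf_floor <- function(n_samples) {
  if (!is_count(n_samples)) {
    abort_validation("`n_samples` must be a positive integer.")
  }
  1 / (2 * n_samples)
}

#' Annotate a variant table with class, damage, rarity and constraint flags
#'
#' Convenience wrapper adding `variant_class`, `damaging`, `rare` (and, when
#' a constraint table is given, `intolerant_pli`/`intolerant_loeuf`) columns.
#'
#' @param variants Variant tibble (`consequence`, `cadd`, panel count columns).
#' @param constraint Optional constraint tibble.
#' @param panels Panels used for the rarity call; default all present.
#' @param maf_threshold,cadd_threshold Rarity and damage thresholds.
#' @return The annotated tibble.
#' @export
annotate_variants <- function(variants, constraint = NULL, panels = NULL,
                              maf_threshold = 0.01, cadd_threshold = 20) {
  out <- variants |>
    dplyr::mutate(
      variant_class = classify_consequence(.data$consequence),
      damaging = is_damaging(.data$cadd, cadd_threshold),
      rare = is_rare(variants, panels, maf_threshold)
    )
  if (!is.null(constraint)) {
    out <- dplyr::left_join(
      out,
      constraint_flags(unique(out$gene), constraint),
      by = "gene"
    )
  }
  out
}
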