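# Readers and writers for every external format the pipeline touches.
#
# Coordinate convention: intervals (BED, SV tables, gene intervals) are
# 0-based half-open everywhere inside the package; VCF positions are 1-based
# as in the format. Readers validate and reject rather than silently coerce;
# errors carry file, line and field. Unknown INFO keys are ignored with a
# notice (annotator outputs differ); panel frequencies are carried as
# allele-count pairs, not floats, so downstream 2x2 tables are exact.

parse_info <- function(info) {
  out <- list()
  for (kv in strsplit(info, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    } else if (nzchar(kv)) {
      out[[kv]] <- "TRUE"
    }
  }
  out
}

# k-th comma-separated token (per-ALT values), recycling scalars.
info_allele <- function(value, k) {
  if (is.null(value)) return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts else parts[k]
}

num_or_na <- function(x) {
  ifelse(is.na(x) | x == ".", NA_real_, suppressWarnings(as.numeric(x)))
}

# Count alleles of index k across GT strings; returns list(dosage, an_contrib).
# vcfR reports fully missing genotypes as NA.
gt_allele_counts <- function(gt_fields, k, path, line) {
  gt_fields[is.na(gt_fields)] <- "./."
  alleles <- strsplit(gsub("|", "/", gt_fields, fixed = TRUE), "/", fixed = TRUE)
  bad <- vapply(alleles, function(a) {
    !all(a %in% c(".", as.character(0:99)))
  }, logical(1))
  if (any(bad)) {
    abort_format(sprintf("%s record %d: malformed GT field `%s`.",
                         path, line, gt_fields[which(bad)[1]]))
  }
  dosage <- vapply(alleles, function(a) {
    if (all(a == ".")) NA_integer_ else sum(a == as.character(k))
  }, integer(1))
  an <- vapply(alleles, function(a) sum(a != "."), integer(1))
  list(dosage = dosage, an = sum(an))
}

#' Read an annotated cohort VCF
#'
#' Parses a VCF v4.2 with `GENE`, `CSQ` and `CADD` INFO annotations and
#' per-panel allele counts (`AC_PANEL_<name>` / `AN_PANEL_<name>`).
#' Multiallelic records are split into one row per ALT allele before
#' anything else. Case allele counts are recomputed from the GT fields when
#' samples are present (allele number = 2 x non-missing samples), otherwise
#' taken from the `AC`/`AN` INFO keys.
#'
#' @param path VCF file path.
#' @param genotypes Keep per-sample dosages as a `gt` list-column.
#' @return Variant tibble (`chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `cadd`, `ac_case`, `an_case`, `ac_<panel>`/`an_<panel>`,
#'   optional `gt`), with attribute `n_samples` (header sample count).
#' @export
read_variant_vcf <- function(path, genotypes = TRUE) {
  if (!file.exists(path)) abort_format(sprintf("VCF not found: %s", path))
  first <- readLines(path, n = 1)
  if (!length(first) || !startsWith(first, "##fileformat=VCF")) {
    abort_format(sprintf("%s: missing ##fileformat VCF header.", path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt_mat <- vcf@gt
  samples <- if (!is.null(colnames(gt_mat)) && ncol(gt_mat) > 1) {
    colnames(gt_mat)[-1]
  } else {
    character(0)
  }
  rows <- list()
  unknown_keys <- character(0)
  known_keys <- c("GENE", "CSQ", "CADD", "AC", "AN", "AF")

  for (i in seq_len(nrow(fix))) {
    info <- parse_info(fix[i, "INFO"])
    keys <- names(info)
    unknown_keys <- union(unknown_keys,
                          keys[!keys %in% known_keys &
                                 !grepl("^(AC|AN|AF)_PANEL_", keys)])
    for (req in c("GENE", "CSQ")) {
      if (is.null(info[[req]])) {
        abort_format(sprintf("%s record %d: required INFO key `%s` missing.",
                             path, i, req))
      }
    }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    panel_keys <- grep("^AC_PANEL_", keys, value = TRUE)
    has_gt <- length(samples) > 0 && nrow(gt_mat) >= i

    for (k in seq_along(alts)) {
      if (alts[k] == fix[i, "REF"]) {
        abort_format(sprintf("%s record %d: ALT equals REF.", path, i))
      }
      row <- list(
        chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]), alt = alts[k],
        gene = info_allele(info$GENE, k),
        consequence = info_allele(info$CSQ, k),
        cadd = num_or_na(info_allele(info$CADD, k))
      )
      if (has_gt) {
        cnt <- gt_allele_counts(unname(gt_mat[i, -1]), k, path, i)
        row$ac_case <- as.integer(sum(cnt$dosage, na.rm = TRUE))
        row$an_case <- as.integer(cnt$an)
        if (genotypes) row$gt <- list(setNames(cnt$dosage, samples))
      } else {
        row$ac_case <- as.integer(num_or_na(info_allele(info$AC, k)))
        row$an_case <- as.integer(num_or_na(info_allele(info$AN, k)))
      }
      for (pk in panel_keys) {
        pname <- sub("^AC_PANEL_", "", pk)
        row[[paste0("ac_", pname)]] <-
          as.integer(num_or_na(info_allele(info[[pk]], k)))
        row[[paste0("an_", pname)]] <-
          as.integer(num_or_na(info_allele(info[[paste0("AN_PANEL_", pname)]], 1)))
      }
      rows[[length(rows) + 1]] <- tibble::as_tibble(row)
    }
  }
  if (length(unknown_keys) > 0) {
    notify(sprintf("Ignoring unknown INFO key(s): %s",
                   paste(sort(unknown_keys), collapse = ", ")))
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), gene = character(),
                   consequence = character(), cadd = numeric(),
                   ac_case = integer(), an_case = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  bad <- which(out$ac_case > out$an_case)
  if (length(bad) > 0) {
    abort_format(sprintf("%s: allele count exceeds allele number at %s:%d.",
                         path, out$chrom[bad[1]], out$pos[bad[1]]))
  }
  attr(out, "n_samples") <- length(samples)
  out
}

fmt_info_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
}

#' Write a cohort variant table as VCF v4.2
#'
#' Emits one biallelic record per variant with `GENE`/`CSQ`/`CADD` and
#' per-panel count annotations; missing CADD scores are written as `.`.
#' With a `gt` list-column, per-sample GT fields are written (dosage 0/1/2 as
#' 0/0, 0/1, 1/1; missing as ./.), otherwise `AC`/`AN` INFO keys carry the
#' case counts. `read_variant_vcf()` round-trips the output field for field.
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  panels <- panel_names(variants)
  has_gt <- "gt" %in% names(variants) && nrow(variants) > 0
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>",
            unique(if (nrow(variants)) variants$chrom else "chrS")),
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Case alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Case allele number\">",
    unlist(lapply(panels, function(p) c(
      sprintf("##INFO=<ID=AC_PANEL_%s,Number=A,Type=Integer,Description=\"Panel %s allele count\">", p, p),
      sprintf("##INFO=<ID=AN_PANEL_%s,Number=1,Type=Integer,Description=\"Panel %s allele number\">", p, p),
      sprintf("##INFO=<ID=AF_PANEL_%s,Number=A,Type=Float,Description=\"Panel %s allele frequency\">", p, p)
    ))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  sample_ids <- if (has_gt) names(variants$gt[[1]]) else character(0)
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", if (has_gt) c("FORMAT", sample_ids)),
                      collapse = "\t")
  records <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    info <- c(
      sprintf("GENE=%s", variants$gene[i]),
      sprintf("CSQ=%s", variants$consequence[i]),
      sprintf("CADD=%s", fmt_info_num(variants$cadd[i])),
      if (!has_gt) c(sprintf("AC=%d", variants$ac_case[i]),
                     sprintf("AN=%d", variants$an_case[i]))
    )
    for (p in panels) {
      ac <- variants[[paste0("ac_", p)]][i]
      an <- variants[[paste0("an_", p)]][i]
      info <- c(info,
                sprintf("AC_PANEL_%s=%s", p, fmt_info_num(ac)),
                sprintf("AN_PANEL_%s=%s", p, fmt_info_num(an)),
                sprintf("AF_PANEL_%s=%s", p,
                        fmt_info_num(if (!is.na(an) && an > 0) ac / an else NA)))
    }
    fields <- c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
                variants$alt[i], ".", "PASS", paste(info, collapse = ";"))
    if (has_gt) {
      gt_str <- c("0/0", "0/1", "1/1")[variants$gt[[i]] + 1L]
      gt_str[is.na(gt_str)] <- "./."
      fields <- c(fields, "GT", gt_str)
    }
    records[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(header, chrom_line, records), path)
  invisible(path)
}

#' Read a gene constraint table
#'
#' TSV with header columns `gene`, `pli`, `loeuf` and optionally `loeuf_bin`.
#' Rejects duplicate genes and out-of-domain scores.
#'
#' @param path TSV path.
#' @return Tibble, one row per gene.
#' @export
read_constraint_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("gene", "pli", "loeuf")
  if (!all(req %in% names(tab))) {
    abort_format(sprintf("%s: missing column(s) %s.", path,
                         paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  if (!"loeuf_bin" %in% names(tab)) tab$loeuf_bin <- NA_integer_
  dup <- unique(tab$gene[duplicated(tab$gene)])
  if (length(dup) > 0) {
    abort_validation(sprintf("%s: duplicated gene(s): %s.", path,
                             paste(dup, collapse = ", ")))
  }
  bad <- which(is.na(tab$pli) | tab$pli < 0 | tab$pli > 1)
  if (length(bad) > 0) {
    abort_validation(sprintf("%s line %d: field `pli` outside [0, 1] for %s.",
                             path, bad[1] + 1L, tab$gene[bad[1]]))
  }
  bad <- which(is.na(tab$loeuf) | tab$loeuf < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf("%s line %d: field `loeuf` must be >= 0 for %s.",
                             path, bad[1] + 1L, tab$gene[bad[1]]))
  }
  bad <- which(!is.na(tab$loeuf_bin) & !tab$loeuf_bin %in% 0:9)
  if (length(bad) > 0) {
    abort_validation(sprintf("%s line %d: field `loeuf_bin` outside 0-9 for %s.",
                             path, bad[1] + 1L, tab$gene[bad[1]]))
  }
  tab$loeuf_bin <- as.integer(tab$loeuf_bin)
  tibble::as_tibble(tab)
}

#' Read a BED3 region file
#'
#' Intervals are kept in BED's native 0-based half-open convention, which is
#' also the package's internal convention (a line `chr1 0 100` covers 1-based
#' positions 1-100).
#'
#' @param path BED path (no header).
#' @param name Region-set label, recorded in the `set` column.
#' @return Tibble `chrom`, `start`, `end`, `set`; queries downstream are
#'   independent of row order.
#' @export
read_regions_bed <- function(path, name = basename(path)) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end <= tab$start |
                 tab$start < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "%s line %d: invalid interval (end must exceed start >= 0).",
      path, bad[1]))
  }
  dplyr::mutate(tibble::as_tibble(tab), set = name)
}

#' Write regions as BED3
#' @param regions Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  readr::write_tsv(regions[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a structural-variant call table
#'
#' TSV with header columns `chrom`, `start`, `end` (0-based half-open),
#' `sv_type` (DEL/DUP), optional `sv_id`, any number of `carriers_<cohort>`
#' columns, and optional logical evidence / class columns.
#'
#' @param path TSV path.
#' @param cohort_sizes Optional named sizes; carrier counts are validated
#'   against them.
#' @return SV tibble.
#' @export
read_sv_calls <- function(path, cohort_sizes = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("chrom", "start", "end", "sv_type")
  if (!all(req %in% names(tab))) {
    abort_format(sprintf("%s: missing column(s) %s.", path,
                         paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  bad <- which(tab$end <= tab$start)
  if (length(bad) > 0) {
    abort_validation(sprintf("%s line %d: end must exceed start.",
                             path, bad[1] + 1L))
  }
  bad <- which(!tab$sv_type %in% c("DEL", "DUP"))
  if (length(bad) > 0) {
    abort_validation(sprintf("%s line %d: sv_type must be DEL or DUP.",
                             path, bad[1] + 1L))
  }
  if (!"sv_id" %in% names(tab)) {
    tab$sv_id <- sprintf("%s:%d-%d:%s", tab$chrom, tab$start, tab$end,
                         tab$sv_type)
  }
  if (!is.null(cohort_sizes)) {
    for (cohort in names(cohort_sizes)) {
      col <- paste0("carriers_", cohort)
      if (col %in% names(tab)) {
        bad <- which(tab[[col]] > cohort_sizes[[cohort]])
        if (length(bad) > 0) {
          abort_validation(sprintf(
            "%s line %d: field `%s` exceeds the %s cohort size (%d).",
            path, bad[1] + 1L, col, cohort, cohort_sizes[[cohort]]))
        }
      }
    }
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tibble::as_tibble(tab)
}

#' Write a structural-variant call table
#' @param svs SV tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(svs, path) {
  readr::write_tsv(svs, path)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV (RFC 4180) with header: `subject_id`, `age`, `sex`, `thi`, `tfi`, the
#' comorbidity flags (logical), and `duration_category` from the fixed
#' vocabulary (6m-3y, 3-10y, 10-20y, >20y, missing).
#'
#' @param path CSV path.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("subject_id", "thi", "tfi", "duration_category")
  if (!all(req %in% names(tab))) {
    abort_format(sprintf("%s: missing column(s) %s.", path,
                         paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  for (score in c("thi", "tfi")) {
    bad <- which(is.na(tab[[score]]) | tab[[score]] < 0 | tab[[score]] > 100)
    if (length(bad) > 0) {
      abort_validation(sprintf("%s line %d: field `%s` outside [0, 100].",
                               path, bad[1] + 1L, score))
    }
  }
  bad <- which(!tab$duration_category %in% .DURATION_LEVELS)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "%s line %d: field `duration_category` not in {%s}.",
      path, bad[1] + 1L, paste(.DURATION_LEVELS, collapse = ", ")))
  }
  tibble::as_tibble(tab)
}

#' Write a clinical table as CSV
#' @param records Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read an expression matrix (probes x regions)
#'
#' TSV with columns `probe_id`, `gene`, then one numeric column per region.
#'
#' @param path TSV path.
#' @return Expression tibble.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("probe_id", "gene") %in% names(tab))) {
    abort_format(sprintf("%s: needs `probe_id` and `gene` columns.", path))
  }
  if (anyDuplicated(tab$probe_id)) {
    abort_validation(sprintf("%s: duplicated probe ids.", path))
  }
  tibble::as_tibble(tab)
}
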