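# Shared fixtures, all built in code.

small_config <- function(seed = 42, ...) {
  simulation_config(n_genes = 8, variants_per_gene = 5, seed = seed, ...)
}

planted_config <- function(seed = 42, target_or = 4,
                           variant_class = "MISSENSE", ...) {
  simulation_config(
    n_genes = 8, variants_per_gene = 8, seed = seed,
    enriched_genes = tibble::tibble(gene = "GENE0001",
                                    target_or = target_or,
                                    variant_class = variant_class),
    ...
  )
}

# Independent Pearson chi-squared oracle: sum over all four cells of
# (observed - expected)^2 / expected under the independence margins.
chi2_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expected)^2 / expected)
}

# Brute-force per-base coverage: fraction of the SV's bases falling in the
# union of the regions (all coordinates 0-based half-open, small enough to
# enumerate).
covered_fraction_bruteforce <- function(sv_start, sv_end, regions) {
  sv_bases <- seq(sv_start, sv_end - 1)
  region_bases <- unique(unlist(Map(function(s, e) seq(s, e - 1),
                                    regions$start, regions$end)))
  mean(sv_bases %in% region_bases)
}

reciprocal_overlap_bruteforce <- function(a_start, a_end, b_start, b_end) {
  a <- seq(a_start, a_end - 1)
  b <- seq(b_start, b_end - 1)
  length(intersect(a, b)) / max(length(a), length(b))
}

# Exact binomial 99% interval for an observed proportion under n trials.
binom99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}

# A tiny hand-written VCF with a multiallelic record and known allele counts.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"d\">",
    "##INFO=<ID=AC_PANEL_ref,Number=A,Type=Integer,Description=\"a\">",
    "##INFO=<ID=AN_PANEL_ref,Number=1,Type=Integer,Description=\"n\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "T", ".", "PASS",
            "GENE=G1;CSQ=missense_variant;CADD=23.1;AC_PANEL_ref=5;AN_PANEL_ref=2000",
            "GT", "0/1", "0/1", "1/1"), collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "C,T", ".", "PASS",
            "GENE=G1,G2;CSQ=synonymous_variant,stop_gained;CADD=1.2,35.0;AC_PANEL_ref=10,0;AN_PANEL_ref=2000",
            "GT", "1/2", "0/0", "./."), collapse = "\t"),
    paste(c("chr1", "300", ".", "T", "G", ".", "PASS",
            "GENE=G2;CSQ=stop_gained;CADD=.;AC_PANEL_ref=0;AN_PANEL_ref=2000",
            "GT", "0/0", "0/1", "0/0"), collapse = "\t")
  ), path)
  path
}
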