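# Packaged worked example: the 12 both-method candidate codons in MAMLD1,
# PRDM9 and ZNF860, with the population frequencies, LD block and
# archaic/ape states reported for them, plus the five human-branch candidate
# genes. Frequencies not printed for two rare PRDM9 back-variants (codons
# 629/657, described only as "rare") are synthetic placeholders of 0.01.

#' Candidate-site fixture: the 12 both-method codons in three genes
#'
#' Twelve records across MAMLD1 (2), PRDM9 (7) and ZNF860 (3): codon change,
#' SNP id where one exists, ancestral-allele frequency, LD partners (the
#' ZNF860 348-464-609 haplo-block; 609 is a site detected by the per-site
#' test only, so it appears as a partner but not as a record), archaic state
#' and great-ape panel variation, along with the reported decision for each
#' site.
#'
#' @return data.frame with 12 rows; `ld_partners` is a list-column of integer
#'   vectors.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_sites.tsv", package = "primsel",
                      mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  x$ld_partners <- lapply(strsplit(ifelse(is.na(x$ld_partners), "",
                                          x$ld_partners), "\\|"),
                          function(v) as.integer(v[nzchar(v)]))
  # invariant: codon strings are length-3 over ACGT
  codons <- unlist(strsplit(x$codon_change, "[>|]"))
  stopifnot(all(nchar(codons) == 3L),
            !grepl("[^ACGT]", paste(codons, collapse = "")),
            nrow(x) == 12L, length(unique(x$gene)) == 3L)
  x
}

#' The five human-branch candidate genes
#'
#' Gene-level metadata for the five genes flagged by both gene-level tests on
#' the human terminal branch: family annotation (four of five are KRAB
#' zinc-finger proteins) and the number of both-method candidate sites.
#'
#' @return data.frame with columns gene, family, krab_znf, consensus_sites.
#' @export
human_branch_candidates <- function() {
  path <- system.file("extdata", "human_branch_genes.tsv",
                      package = "primsel", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Population-variation tables for the candidate-site fixture
#'
#' Expands [table2_fixture()] into the long per-population variant table and
#' the phased haplotype panel that the verification cascade consumes. Sites
#' without a recorded SNP have no variant rows. The ZNF860 block (codons 348,
#' 464 and the per-site-test-only partner 609) gets a deterministic
#' comonotone haplotype panel whose pairwise r-squared with the block centre
#' falls in the reported 0.5-1 range.
#'
#' @return List with `variants` (gene, codon_index, snp_id, pop,
#'   derived_freq), `haplotypes` (1000 x 3 0/1 matrix, columns
#'   `ZNF860:{348,464,609}`) and `archaic`, `ape_variation` lookups.
#' @export
table2_variants <- function() {
  fx <- table2_fixture()
  rows <- list(
    data.frame(gene = "PRDM9", codon_index = 573, snp_id = "rs199686868",
               pop = "GWD", derived_freq = 0.98),
    data.frame(gene = "PRDM9", codon_index = 591, snp_id = "rs200381384",
               pop = "KOR", derived_freq = 0.94),
    data.frame(gene = "PRDM9", codon_index = 629, snp_id = "rs112192848",
               pop = "ALL", derived_freq = 0.99),
    data.frame(gene = "PRDM9", codon_index = 657, snp_id = "rs112679149",
               pop = "ALL", derived_freq = 0.99),
    data.frame(gene = "PRDM9", codon_index = 681, snp_id = "rs6875787",
               pop = "ALL", derived_freq = 0.25),
    data.frame(gene = "ZNF860", codon_index = 348, snp_id = "rs13064905",
               pop = c("AFR", "EUR"), derived_freq = c(0.20, 0.70)),
    data.frame(gene = "ZNF860", codon_index = 464, snp_id = "rs1808125",
               pop = c("AFR", "EUR"), derived_freq = c(0.10, 0.72)),
    data.frame(gene = "ZNF860", codon_index = 609, snp_id = "rs1808126",
               pop = c("AFR", "EUR"), derived_freq = c(0.15, 0.71))
  )
  variants <- do.call(rbind, rows)

  # deterministic comonotone panel for the ZNF860 haplo-block
  # (ancestral-allele indicators at ancestral frequencies 0.80/0.90/0.85)
  u <- (seq_len(1000) - 0.5) / 1000
  hap <- cbind(`ZNF860:348` = as.integer(u < 0.80),
               `ZNF860:464` = as.integer(u < 0.90),
               `ZNF860:609` = as.integer(u < 0.85))

  archaic <- data.frame(gene = fx$gene, codon_index = fx$codon_index,
                        Vindija = fx$archaic_state, Altai = fx$archaic_state,
                        Denisova = fx$archaic_state)
  list(variants = variants, haplotypes = hap,
       archaic = archaic,
       ape_variation = fx[, c("gene", "codon_index", "ape_variation")])
}
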