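test_that("r-squared follows the closed form", {
  expect_equal(as.numeric(compute_r2(c(1, 0, 1, 0), c(1, 0, 1, 0))), 1)
  # counts AB=40, ab=40, Ab=10, aB=10: D = 0.15, r2 = 0.36
  a <- c(rep(1, 40), rep(0, 40), rep(1, 10), rep(0, 10))
  b <- c(rep(1, 40), rep(0, 40), rep(0, 10), rep(1, 10))
  expect_equal(as.numeric(compute_r2(a, b)), 0.36, tolerance = 1e-12)
  # independent sites are near zero
  set.seed(6)
  x <- rbinom(10000, 1, 0.3); y <- rbinom(10000, 1, 0.6)
  expect_lt(as.numeric(compute_r2(x, y)), 0.05)
  mono <- compute_r2(rep(1, 5), c(0, 1, 0, 1, 1))
  expect_equal(as.numeric(mono), 0)
  expect_match(attr(mono, "note"), "monomorphic")
  expect_error(compute_r2(1:4, 1:5), "length")
})

test_that("classification rules fire in order", {
  th <- verification_thresholds()
  cand <- data.frame(gene = "G", codon_index = 1:5)
  variants <- rbind(
    data.frame(gene = "G", codon_index = 2, snp_id = "rs2", pop = "P1",
               derived_freq = 0.97),                    # rare back-variant
    data.frame(gene = "G", codon_index = 3, snp_id = "rs3", pop = "P1",
               derived_freq = 0.30),                    # minor allele
    data.frame(gene = "G", codon_index = 4, snp_id = "rs4", pop = "P1",
               derived_freq = 0.25),                    # in LD block
    data.frame(gene = "G", codon_index = 5, snp_id = "rs5", pop = "P1",
               derived_freq = NA))                      # no frequency data
  ld <- diag(1, 2)
  dimnames(ld) <- list(c("G:4", "G:9"), c("G:4", "G:9"))
  ld["G:4", "G:9"] <- ld["G:9", "G:4"] <- 0.8
  dec <- classify_pss(cand, variants, ld, th)
  expect_equal(dec$call,
               c("TRUE_PSS", "TRUE_PSS", "MINOR_ALLELE", "FALSE_POSITIVE",
                 "UNRESOLVED"))
  expect_equal(dec$reason[1], "no_modern_polymorphism")
  expect_equal(dec$reason[2], "rare_independent_backvariant")
  expect_equal(dec$reason[4], "ancestral_standing_variation_haploblock")

  # partition: one call per candidate, order-invariant
  perm <- c(4, 2, 5, 1, 3)
  dec2 <- classify_pss(cand[perm, ], variants, ld, th)
  expect_equal(dec2$call[order(dec2$codon_index)],
               dec$call[order(dec$codon_index)])
  expect_equal(nrow(dec), nrow(cand))
})

test_that("LD only counts sites within the same gene", {
  cand <- data.frame(gene = c("G1", "G2"), codon_index = c(1, 1))
  variants <- data.frame(gene = c("G1", "G2"), codon_index = 1,
                         snp_id = c("a", "b"), pop = "P",
                         derived_freq = 0.2)
  ld <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("G1:1", "G2:1"), c("G1:1", "G2:1")))
  dec <- classify_pss(cand, variants, ld)
  # cross-gene r2 of 0.9 must not create a haplo-block
  expect_true(all(dec$call == "MINOR_ALLELE"))
})

test_that("archaic dating follows the genotype rules", {
  dec <- data.frame(gene = "G", codon_index = 1:3,
                    call = c("TRUE_PSS", "TRUE_PSS", "TRUE_PSS"))
  arch <- data.frame(gene = "G", codon_index = 1:3,
                     Vindija = c("derived", "heterozygous", "missing"),
                     Altai = c("derived", "derived", "missing"),
                     Denisova = c("missing", "derived", "missing"))
  out <- archaic_dating(dec, arch)
  expect_equal(out$dating, c("PRE_ARCHAIC_SPLIT", "POST_ARCHAIC_SPLIT",
                             "UNDATED"))
  # non-true calls receive no dating
  dec$call[1] <- "MINOR_ALLELE"
  expect_true(is.na(archaic_dating(dec, arch)$dating[1]))
  empty <- archaic_dating(dec[0, ], arch)
  expect_equal(nrow(empty), 0)
})

test_that("ape panel summary classifies per-taxon variation", {
  g <- simulate_archaic_and_ape_genotypes(sites = c(7, 8),
                                          ape_variation = c("none",
                                                            "variable"),
                                          seed = 3)
  s7 <- ape_panel_summary(codon_index = 7, ape_tab = g$ape)
  expect_true(all(s7 == "monomorphic-ancestral"))
  expect_match(attr(s7, "note"), "lineage sorting")
  s8 <- ape_panel_summary(codon_index = 8, ape_tab = g$ape)
  expect_true(any(s8 == "polymorphic"))
  s9 <- ape_panel_summary(codon_index = 99, ape_tab = g$ape)
  expect_true(all(s9 == "missing"))
})

test_that("the packaged candidate-site fixture is faithful", {
  fx <- table2_fixture()
  expect_equal(nrow(fx), 12)
  expect_equal(sort(unique(fx$gene)), c("MAMLD1", "PRDM9", "ZNF860"))
  expect_equal(sum(fx$gene == "MAMLD1"), 2)
  expect_equal(sum(fx$gene == "PRDM9"), 7)
  expect_equal(sum(fx$gene == "ZNF860"), 3)
  r726 <- fx[fx$gene == "MAMLD1" & fx$codon_index == 726, ]
  expect_equal(r726$codon_change, "AGT>AGA")
  expect_true(is.na(r726$snp_id))
  r681 <- fx[fx$gene == "PRDM9" & fx$codon_index == 681, ]
  expect_equal(r681$snp_id, "rs6875787")
  expect_equal(r681$ancestral_freq, 0.75)
  r348 <- fx[fx$gene == "ZNF860" & fx$codon_index == 348, ]
  expect_setequal(r348$ld_partners[[1]], c(464L, 609L))
})
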