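test_that("simulation is deterministic and honors degenerate settings", {
  tr <- toy_tree4()
  mix <- site_class_mixture(0.5, 0.4, 0.1, 3)
  cfg <- simulation_config(tr, 50, mix, seed = 99)
  s1 <- simulate_codon_alignment(cfg)
  s2 <- simulate_codon_alignment(cfg)
  expect_identical(s1$aln$codons, s2$aln$codons)
  expect_identical(s1$classes, s2$classes)

  # zero branch lengths: all rows equal the ancestral sequence
  tr0 <- toy_tree4()
  tr0$edge.length[] <- 0
  s0 <- simulate_codon_alignment(simulation_config(tr0, 30, mix, seed = 1))
  expect_true(all(apply(s0$aln$codons, 2, function(x) length(unique(x))) == 1))

  # p2 = 0: omega2 is irrelevant at the same seed
  mA <- site_class_mixture(0.6, 0.4, 0.2, omega2 = 1)
  mB <- site_class_mixture(0.6, 0.4, 0.2, omega2 = 9)
  sA <- simulate_codon_alignment(simulation_config(tr, 40, mA, seed = 3))
  sB <- simulate_codon_alignment(simulation_config(tr, 40, mB, seed = 3))
  expect_identical(sA$aln$codons, sB$aln$codons)
})

test_that("class labels converge to mixture proportions", {
  tr <- toy_tree4()
  mix <- site_class_mixture(0.45, 0.35, 0.1, 4)
  n <- 4000
  sim <- simulate_codon_alignment(simulation_config(tr, n, mix, seed = 13))
  p2 <- mix$p2a + mix$p2b
  frac2 <- mean(sim$classes >= 2)
  expect_lt(abs(frac2 - p2), 3 * sqrt(p2 * (1 - p2) / n))
})

test_that("tip codon distribution approaches stationarity on a long branch", {
  tr <- ape::read.tree(text = "(A:50,B:0.001);")
  tr <- mark_foreground(tr, "A")
  mix <- site_class_mixture(1, 0, omega0 = 1, omega2 = 1)
  sim <- simulate_codon_alignment(simulation_config(tr, 200000, mix,
                                                    seed = 17))
  freq <- table(factor(sim$aln$codons["A", ], levels = sense_codons()))
  tv <- 0.5 * sum(abs(freq / sum(freq) - mix$pi))
  expect_lt(tv, 0.01)
})

test_that("variant simulation hits target frequencies and LD", {
  cfg <- variant_sim_config(sites = 1:3,
                           freq = list(POP = c(0.25, 0.25, 0.25)),
                           panel_sizes = c(POP = 10000),
                           ld_blocks = list(list(sites = 1:3, r2 = 0.7)),
                           seed = 5)
  vt <- simulate_variant_table(cfg)
  f <- vt$table$derived_freq
  expect_true(all(f >= 0.23 & f <= 0.27))
  r2 <- r2_matrix(vt$haplotypes$POP)
  off <- r2[upper.tri(r2)]
  expect_true(all(abs(off - 0.7) < 0.1))

  # perfect LD with equal frequencies gives identical columns
  cfg1 <- variant_sim_config(1:2, list(P = c(0.4, 0.4)), c(P = 500),
                             list(list(sites = 1:2, r2 = 1)), seed = 2)
  h <- simulate_variant_table(cfg1)$haplotypes$P
  expect_identical(h[, 1], h[, 2])

  # fixed derived allele: no polymorphism recorded
  cfg2 <- variant_sim_config(1:2, list(P = c(1, 0.3)), c(P = 100), seed = 3)
  tab2 <- simulate_variant_table(cfg2)$table
  expect_false(1 %in% tab2$site)
  expect_true(2 %in% tab2$site)

  # unattainable r2 for unequal frequencies is an error
  cfg3 <- variant_sim_config(1:2, list(P = c(0.5, 0.95)), c(P = 100),
                             list(list(sites = 1:2, r2 = 0.9)), seed = 4)
  expect_error(simulate_variant_table(cfg3), "unattainable")

  # each site in at most one block
  expect_error(variant_sim_config(1:3, list(P = rep(0.5, 3)), c(P = 10),
                                  list(list(sites = 1:2, r2 = 0.5),
                                       list(sites = 2:3, r2 = 0.5))),
               "at most one")
})

test_that("LD targets are met across block sizes up to 5", {
  for (k in c(2, 5)) {
    cfg <- variant_sim_config(seq_len(k),
                              freq = list(P = rep(0.35, k)),
                              panel_sizes = c(P = 8000),
                              ld_blocks = list(list(sites = seq_len(k),
                                                    r2 = 0.6)),
                              seed = 40 + k)
    r2 <- r2_matrix(simulate_variant_table(cfg)$haplotypes$P)
    expect_true(all(abs(r2[upper.tri(r2)] - 0.6) < 0.1))
  }
})

test_that("archaic and ape genotype simulation honors panel structure", {
  g <- simulate_archaic_and_ape_genotypes(sites = c(10, 20), seed = 1)
  geno_cols <- grep("_[0-9]+$", colnames(g$ape))
  expect_length(geno_cols, 180)
  expect_identical(colnames(g$archaic)[-1], c("Vindija", "Altai", "Denisova"))
  expect_true(all(unlist(g$archaic[, -1]) == "derived"))

  gm <- simulate_archaic_and_ape_genotypes(sites = 1, missing_rate = 1,
                                           seed = 2)
  expect_true(all(unlist(gm$archaic[, -1]) == "missing"))
  expect_error(simulate_archaic_and_ape_genotypes(integer(0)), "non-empty")
})
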