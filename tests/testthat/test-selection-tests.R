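test_that("BH adjustment matches hand computation and is order-preserving", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(25)
  expect_equal(bh_adjust(p), bh_hand(p), tolerance = 1e-12)
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  expect_false(is.unsorted(bh_adjust(sort(p))))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("nested branch-site fits give a clamped nonnegative statistic", {
  tr <- small_primate_tree()
  sim <- simulate_codon_alignment(
    simulation_config(tr, 80, site_class_mixture(0.5, 0.4, 0.1, 1), seed = 2))
  res <- branch_site_lrt(sim$aln, tr, nstarts = 1)
  expect_gte(res$statistic, 0)
  expect_gte(res$lnL1, res$lnL0 - 1e-6)
  expect_true(res$p >= 0 && res$p <= 1)
  # p monotone decreasing in the statistic under both references
  s <- c(0.5, 1, 3)
  for (nd in c("chisq1", "mixture")) {
    p3 <- vapply(s, primsel:::.lrt_pvalue, numeric(1), null_dist = nd)
    expect_true(all(diff(p3) < 0))
  }
  expect_error(branch_site_lrt(sim$aln, build_default_tree(0.05)),
               "foreground")
})

test_that("branch-site test detects strong foreground selection", {
  tr <- small_primate_tree()
  mixA <- site_class_mixture(0.45, 0.4, omega0 = 0.1, omega2 = 10)
  hits <- vapply(1:4, function(i) {
    sim <- simulate_codon_alignment(simulation_config(tr, 150, mixA,
                                                      seed = 500 + i))
    branch_site_lrt(sim$aln, tr, nstarts = 1, seed = i)$p
  }, numeric(1))
  expect_gte(mean(hits < 0.05), 0.5)
})

test_that("BEB grid posterior equals direct summation and sums to one", {
  tr <- toy_tree4()
  mix_sim <- site_class_mixture(0.5, 0.35, 0.15, 6, 2)
  sim <- simulate_codon_alignment(simulation_config(tr, 8, mix_sim, seed = 4))
  mle <- site_class_mixture(0.5, 0.35, 0.2, 4, 2,
                            pi = codon_frequencies(sim$aln, "F3x4"))
  beb <- beb_posteriors(sim$aln, tr, mle)
  expect_true(all(beb$beb_posterior >= 0 & beb$beb_posterior <= 1))
  cp <- attr(beb, "class_posterior")
  expect_equal(colSums(cp), rep(1, ncol(cp)), tolerance = 1e-9)
  expect_equal(beb$beb_posterior, beb_direct(sim$aln, tr, mle),
               tolerance = 1e-10)
  expect_error(beb_posteriors(sim$aln, tr, mle, grid_n = 1), "degenerate")
})

test_that("BEB separates selected from purifying sites on average", {
  tr <- small_primate_tree()
  mixA <- site_class_mixture(0.45, 0.4, omega0 = 0.1, omega2 = 10)
  diffs <- vapply(1:5, function(i) {
    sim <- simulate_codon_alignment(simulation_config(tr, 100, mixA,
                                                      seed = 600 + i))
    bs <- branch_site_lrt(sim$aln, tr, nstarts = 1, seed = i)
    beb <- beb_posteriors(sim$aln, tr, bs$fit1$mix, scale = bs$scale)
    mean(beb$beb_posterior[sim$classes >= 2]) -
      mean(beb$beb_posterior[sim$classes < 2])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("MEME-style site test handles invariant and missing sites", {
  tr <- toy_tree4()
  m <- matrix("ATG", 4, 3, dimnames = list(c("A", "B", "C", "D"), NULL))
  m[, 3] <- "---"
  aln <- codon_alignment(m)
  res <- meme_like_site_test(aln, tr, kappa = 2, scale = 1)
  expect_equal(res$p, rep(1, 3))
  expect_identical(res$note, c("invariant", "invariant", "no data"))
})

test_that("MEME-style test ranks episodic sites highly", {
  tr <- small_primate_tree()
  mixA <- site_class_mixture(0.42, 0.4, omega0 = 0.1, omega2 = 15)
  ranks <- vapply(1:5, function(i) {
    sim <- simulate_codon_alignment(simulation_config(tr, 80, mixA,
                                                      seed = 700 + i))
    res <- meme_like_site_test(sim$aln, tr)
    sel <- which(sim$classes >= 2)
    # fraction of truly selected sites ranked in the top quartile by p
    thresh <- quantile(res$p, 0.25)
    mean(res$p[sel] <= thresh)
  }, numeric(1))
  expect_gt(mean(ranks), 0.3)
})

test_that("aBSREL-style test is calibrated on null data and detects signal", {
  tr <- small_primate_tree()
  mix0 <- site_class_mixture(0.5, 0.4, 0.1, 1)
  p0 <- vapply(1:6, function(i) {
    sim <- simulate_codon_alignment(simulation_config(tr, 80, mix0,
                                                      seed = 800 + i))
    absrel_like_branch_test(sim$aln, tr, refine_passes = 0)$p
  }, numeric(1))
  expect_lte(sum(p0 < 0.05), 1)

  mixA <- site_class_mixture(0.42, 0.4, omega0 = 0.1, omega2 = 12)
  pA <- vapply(1:4, function(i) {
    sim <- simulate_codon_alignment(simulation_config(tr, 150, mixA,
                                                      seed = 900 + i))
    absrel_like_branch_test(sim$aln, tr)$p
  }, numeric(1))
  expect_gte(mean(pA < 0.05), 0.5)
})

test_that("consensus is an intersection with the expected properties", {
  ga <- data.frame(gene = c("g1", "g2", "g3"), p = c(0.01, 0.2, 0.03))
  gb <- data.frame(gene = c("g3", "g2", "g1"), p = c(0.02, 0.01, 0.04))
  sa <- data.frame(gene = c("g1", "g1", "g3"), site = c(5, 9, 2),
                   flagged = c(TRUE, TRUE, TRUE))
  sb <- data.frame(gene = c("g1", "g3"), site = c(5, 2),
                   flagged = c(TRUE, TRUE))
  cons <- consensus(ga, gb, sa, sb)
  expect_setequal(cons$genes$gene, c("g1", "g3"))
  expect_equal(nrow(cons$sites), 2)
  expect_true(all(paste(cons$sites$gene, cons$sites$site) %in%
                    paste(sa$gene, sa$site)))
  # commutative (up to column naming) and idempotent on the gene set
  cons_rev <- consensus(gb, ga, sb, sa)
  expect_setequal(cons_rev$genes$gene, cons$genes$gene)
  expect_setequal(paste(cons_rev$sites$gene, cons_rev$sites$site),
                  paste(cons$sites$gene, cons$sites$site))
  # empty input list gives an empty consensus
  ga0 <- ga; ga0$p <- 1
  expect_equal(nrow(consensus(ga0, gb, sa, sb)$genes), 0)
  expect_error(consensus(ga, data.frame(gene = "gX", p = 0.01)),
               "universes")
})
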