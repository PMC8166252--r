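test_that("pruning equals exhaustive enumeration on toy trees", {
  pi <- {
    set.seed(1); x <- runif(61, 0.5, 2); x / sum(x)
  }
  p <- codon_params(2.3, 0.6, pi)
  Q <- build_rate_matrix(p)

  tr3 <- toy_tree3()
  P3 <- lapply(tr3$edge.length, function(t) transition_matrix(Q, t, p$pi))
  col3 <- c(A = "ATG", B = "ATA", C = "CTG")
  expect_equal(site_log_likelihood(tr3, col3, P3, p$pi),
               brute_site_loglik(tr3, col3, P3, p$pi), tolerance = 1e-10)

  tr4 <- ape::read.tree(text = "((A:0.15,B:0.3):0.1,(C:0.2,D:0.25):0.3);")
  P4 <- lapply(tr4$edge.length, function(t) transition_matrix(Q, t, p$pi))
  set.seed(8)
  for (i in 1:3) {
    col4 <- setNames(sample(sense_codons(), 4), c("A", "B", "C", "D"))
    expect_equal(site_log_likelihood(tr4, col4, P4, p$pi),
                 brute_site_loglik(tr4, col4, P4, p$pi), tolerance = 1e-10)
  }
})

test_that("missing data conventions hold", {
  p <- codon_params(2, 0.5)
  Q <- build_rate_matrix(p)
  tr3 <- toy_tree3()
  P3 <- lapply(tr3$edge.length, function(t) transition_matrix(Q, t, p$pi))
  expect_equal(site_log_likelihood(tr3, c(A = NA, B = NA, C = NA), P3, p$pi),
               0, tolerance = 1e-12)
  # single-leaf tree: likelihood is the stationary codon frequency
  tr1 <- ape::read.tree(text = "(A:0.5);")
  P1 <- list(transition_matrix(Q, 0.5, p$pi))
  expect_equal(site_log_likelihood(tr1, c(A = "ATG"), P1, p$pi),
               log(p$pi[codon_index("ATG")]), tolerance = 1e-10)
})

test_that("Model A mixture likelihood matches brute force on a toy", {
  tr <- toy_tree4()
  mix_sim <- site_class_mixture(0.5, 0.3, omega0 = 0.2, omega2 = 4,
                                kappa = 2.5)
  sim <- simulate_codon_alignment(simulation_config(tr, 6, mix_sim, seed = 3))
  mix <- site_class_mixture(0.45, 0.35, 0.15, 3.5, 2.2,
                            pi = codon_frequencies(sim$aln, "F3x4"))
  expect_equal(as.numeric(model_A_loglik(sim$aln, tr, mix)),
               brute_modelA_loglik(sim$aln, tr, mix), tolerance = 1e-8)
})

test_that("degenerate mixtures collapse as they must", {
  tr <- toy_tree4()
  sim <- simulate_codon_alignment(
    simulation_config(tr, 30, site_class_mixture(0.6, 0.3, 0.2, 3), seed = 5))
  aln <- sim$aln
  pi <- codon_frequencies(aln, "F3x4")
  ws <- primsel:::likelihood_workspace(aln, tr, pi)

  # p2 = 0: equals the two-class purifying/neutral mixture computed directly
  mix <- site_class_mixture(0.7, 0.3, omega0 = 0.15, omega2 = 7, pi = pi)
  l0 <- primsel:::pattern_loglik(ws, mix$kappa, 0.15)
  l1 <- primsel:::pattern_loglik(ws, mix$kappa, 1)
  direct <- sum(ws$weights *
                  primsel:::mix_logsumexp(rbind(l0, l1), c(0.7, 0.3)))
  expect_equal(as.numeric(model_A_loglik(aln, tr, mix)), direct,
               tolerance = 1e-9)

  # omega2 = 1: null and alternative coincide at identical parameters
  m_null <- site_class_mixture(0.5, 0.3, 0.1, 1, 2, pi = pi)
  m_alt <- site_class_mixture(0.5, 0.3, 0.1, 1 + 1e-12, 2, pi = pi)
  expect_equal(as.numeric(model_A_loglik(aln, tr, m_null)),
               as.numeric(model_A_loglik(aln, tr, m_alt)), tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement on the unrooted tree", {
  # same unrooted tree, two rootings along the central edge
  trA <- ape::read.tree(text = "((A:0.2,B:0.3):0.25,(C:0.15,D:0.1):0.25);")
  trB <- ape::read.tree(text = "((A:0.2,B:0.3):0.5,(C:0.15,D:0.1):0.0);")
  set.seed(21)
  cols <- replicate(6, setNames(sample(sense_codons(), 4),
                                c("A", "B", "C", "D")), simplify = FALSE)
  m <- matrix(unlist(lapply(cols, function(x) x[c("A", "B", "C", "D")])),
              nrow = 4, dimnames = list(c("A", "B", "C", "D"), NULL))
  aln <- codon_alignment(m)
  pi <- codon_frequencies(aln, "F3x4")
  wsA <- primsel:::likelihood_workspace(aln, trA, pi)
  wsB <- primsel:::likelihood_workspace(aln, trB, pi)
  llA <- sum(wsA$weights * primsel:::pattern_loglik(wsA, 2, 0.4))
  llB <- sum(wsB$weights * primsel:::pattern_loglik(wsB, 2, 0.4))
  expect_equal(llA, llB, tolerance = 1e-9)
})

test_that("stored-pass foreground update equals a fresh pruning pass", {
  tr <- small_primate_tree()
  sim <- simulate_codon_alignment(
    simulation_config(tr, 40, site_class_mixture(0.5, 0.4, 0.1, 2), seed = 7))
  ws <- primsel:::likelihood_workspace(sim$aln, tr)
  comps <- primsel:::.modelA_components(ws, scale = 1)
  mix <- site_class_mixture(0.5, 0.3, 0.2, 5, 2, pi = ws$pi)
  via_cache <- comps(mix)
  direct <- primsel:::modelA_class_logliks(ws, mix)
  expect_equal(via_cache, direct, tolerance = 1e-9)
})
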