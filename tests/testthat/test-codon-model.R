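test_that("rate matrix has GY94 structure", {
  p <- codon_params(kappa = 2, omega = 0.5)
  Q <- build_rate_matrix(p)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
  expect_equal(-sum(p$pi * diag(Q)), 1, tolerance = 1e-12)
  # multi-position changes forbidden
  expect_equal(Q["AAA", "CCA"], 0)

  # omega = 0 kills nonsynonymous but not synonymous rates
  Q0 <- build_rate_matrix(codon_params(2, 0))
  expect_equal(Q0["AAA", "GAA"], 0) # K -> E
  expect_gt(Q0["AAA", "AAG"], 0)    # K -> K

  # synonymous transition vs nonsynonymous transversion = kappa / omega
  expect_equal(Q["AAA", "AAG"] / Q["AAA", "AAT"], 2 / 0.5)
})

test_that("rate matrix is time-reversible", {
  p <- codon_params(3, 0.4, pi = {
    set.seed(2); x <- runif(61, 0.5, 2); x / sum(x)
  })
  Q <- build_rate_matrix(p)
  S <- p$pi * Q # S[i, j] = pi_i q_ij, symmetric under detailed balance
  expect_equal(S, t(S), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("transition matrix behaves across time scales", {
  p <- codon_params(2, 0.3)
  Q <- build_rate_matrix(p)
  expect_equal(transition_matrix(Q, 0, p$pi), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_matrix(Q, 0.7, p$pi)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
  expect_true(all(P >= 0))
  # long branches reach the stationary distribution
  Pinf <- transition_matrix(Q, 100, p$pi)
  pi_oracle <- stationary_distribution(Q, p$pi)
  expect_equal(max(abs(sweep(Pinf, 2, pi_oracle))), 0, tolerance = 1e-6)
  expect_equal(pi_oracle, p$pi, tolerance = 1e-9)
  # eigen route agrees with scaling-and-squaring
  expect_equal(P, transition_matrix(Q, 0.7, p$pi, method = "expm"),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(transition_matrix(Q, -1, p$pi), ">= 0")
})

test_that("codon frequency estimators are positive and normalised", {
  set.seed(4)
  m <- matrix(sample(sense_codons(), 40, replace = TRUE), nrow = 4,
              dimnames = list(letters[1:4], NULL))
  aln <- codon_alignment(m)
  for (method in c("F3x4", "F1x4", "equal")) {
    pi <- codon_frequencies(aln, method)
    expect_length(pi, 61)
    expect_true(all(pi > 0))
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
})

test_that("relative class rate is linear in omega and 1 at neutrality", {
  pi <- rep(1 / 61, 61)
  expect_equal(relative_rate(2, 1, pi), 1)
  r0 <- relative_rate(2, 0, pi)
  r2 <- relative_rate(2, 2, pi)
  expect_lt(r0, 1)
  expect_equal(r2 - 1, 1 - r0, tolerance = 1e-12)
})
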