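#' Codon substitution model parameters
#'
#' Bundle of GY94-style parameters: transition/transversion rate ratio
#' `kappa`, nonsynonymous/synonymous rate ratio `omega`, and the equilibrium
#' frequency vector `pi` over the 61 sense codons.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega dN/dS ratio, >= 0.
#' @param pi Frequency vector of length 61, strictly positive, summing to 1.
#' @return An object of class `codon_params`.
#' @export
codon_params <- function(kappa = 2, omega = 1, pi = rep(1 / 61, 61)) {
  stopifnot(is.finite(kappa), kappa > 0, is.finite(omega), omega >= 0,
            length(pi) == 61)
  if (any(pi <= 0)) stop("degenerate pi: all codon frequencies must be > 0")
  pi <- pi / sum(pi)
  structure(list(kappa = kappa, omega = omega, pi = pi),
            class = "codon_params")
}

# Static structure of single-nucleotide codon exchanges: for each ordered
# sense-codon pair differing at exactly one position, whether the change is
# a transition and whether it is nonsynonymous. Computed once at load time.
.codon_pair_structure <- local({
  cod <- .codon_tables$codons
  n <- length(cod)
  ch <- matrix(unlist(strsplit(cod, "")), ncol = 3, byrow = TRUE)
  diffs <- matrix(0L, n, n)
  for (k in 1:3) diffs <- diffs + outer(ch[, k], ch[, k], "!=")
  one <- diffs == 1L
  ts <- matrix(FALSE, n, n)
  for (k in 1:3) {
    dk <- outer(ch[, k], ch[, k], "!=")
    tk <- outer(ch[, k], ch[, k], .is_transition)
    ts <- ts | (one & dk & tk)
  }
  aa <- .codon_tables$aa
  nonsyn <- outer(aa, aa, "!=")
  list(single = one, transition = ts & one, nonsyn = nonsyn & one)
})

#' Build a GY94-style codon rate matrix
#'
#' Off-diagonal rate i -> j is zero unless codons differ at exactly one
#' position; otherwise proportional to `pi[j]`, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. The diagonal makes
#' rows sum to zero and the matrix is scaled so the expected number of
#' substitutions per codon per unit time is 1 (`-sum(pi * diag(Q)) == 1`).
#'
#' @param params A [codon_params()] object.
#' @return 61 x 61 rate matrix with codon row/column names.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "codon_params"))
  st <- .codon_pair_structure
  Q <- matrix(0, 61, 61)
  Q[st$single] <- 1
  Q[st$transition] <- params$kappa
  Q[st$nonsyn] <- Q[st$nonsyn] * params$omega
  Q <- sweep(Q, 2, params$pi, "*")
  diag(Q) <- -rowSums(Q)
  rate <- -sum(params$pi * diag(Q))
  if (rate > 0) Q <- Q / rate
  dimnames(Q) <- list(.codon_tables$codons, .codon_tables$codons)
  Q
}

# Symmetrized eigen-decomposition of a reversible Q. Returns A, B, lambda with
# P(t) = A %*% diag(exp(lambda * t)) %*% B.
eigen_decompose_Q <- function(Q, pi) {
  s <- sqrt(pi)
  S <- Q * (s %o% (1 / s))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / s, B = t(e$vectors) * rep(s, each = 61),
       lambda = e$values)
}

#' Relative substitution rate of a dN/dS class
#'
#' [build_rate_matrix()] normalises every matrix to one expected
#' substitution per codon per unit time. Within a site-class mixture the
#' classes must instead share a single time scale, so the engine multiplies
#' each class's branch lengths by the class rate relative to the neutral
#' (`omega = 1`) matrix: `(syn + omega * nonsyn) / (syn + nonsyn)`, where
#' `syn`/`nonsyn` are the stationary synonymous/nonsynonymous rate flows at
#' the given `kappa` and `pi`. Branch lengths are thus expressed in
#' neutral-equivalent substitutions per codon.
#'
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS of the class.
#' @param pi Codon frequencies.
#' @return Positive scalar (1 when `omega = 1`).
#' @export
relative_rate <- function(kappa, omega, pi) {
  st <- .codon_pair_structure
  W <- matrix(0, 61, 61)
  W[st$single] <- 1
  W[st$transition] <- kappa
  W <- sweep(W, 2, pi, "*") * pi
  syn <- sum(W[st$single & !st$nonsyn])
  nonsyn <- sum(W[st$nonsyn])
  (syn + omega * nonsyn) / (syn + nonsyn)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetrized eigen-decomposition (the chain is time-reversible),
#' with a scaling-and-squaring series fallback available for cross-checking.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @param pi Equilibrium frequencies used to build `Q` (required for the
#'   eigen method; recovered from `Q` if omitted is not supported).
#' @param method `"eigen"` (default) or `"expm"` (scaling and squaring).
#' @return 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t, pi, method = c("eigen", "expm")) {
  method <- match.arg(method)
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  if (method == "eigen") {
    ed <- eigen_decompose_Q(Q, pi)
    P <- ed$A %*% (exp(ed$lambda * t) * ed$B)
  } else {
    P <- expm_ss(Q * t)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# scaling-and-squaring matrix exponential (Taylor at scaled argument);
# used as an independent cross-check of the eigen route
expm_ss <- function(M, order = 12L) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  A <- M / 2^s
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Stationary distribution check helper
#'
#' Returns the stationary distribution of `Q` (the left null vector), used in
#' tests to confirm that `P(t)` rows approach `pi` for large `t`.
#'
#' @param Q Rate matrix.
#' @param pi Frequencies used to build `Q`.
#' @return Numeric vector of length 61.
#' @export
stationary_distribution <- function(Q, pi) {
  ed <- eigen_decompose_Q(Q, pi)
  i0 <- which.min(abs(ed$lambda))
  # left null vector of Q; under reversibility this equals pi
  w <- ed$B[i0, ] / sum(ed$B[i0, ])
  as.numeric(w)
}
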