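# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, naive DP, direct summation) and
# stay independent of the package's computational paths.

# exhaustive site likelihood: sum over all internal-node state assignments
brute_site_loglik <- function(tree, column, Plist, pi) {
  cods <- sense_codons()
  edge <- tree$edge
  n_tip <- ape::Ntip(tree)
  n_node <- max(edge)
  internal <- setdiff(seq_len(n_node), seq_len(n_tip))
  tip_states <- match(column[tree$tip.label], cods)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:61), length(internal))))
  root <- setdiff(edge[, 1], edge[, 2])
  node_states <- function(node) {
    if (node <= n_tip) rep(tip_states[node], nrow(grid))
    else grid[, match(node, internal)]
  }
  pr <- pi[node_states(root)]
  for (e in seq_len(nrow(edge))) {
    pr <- pr * Plist[[e]][cbind(node_states(edge[e, 1]),
                                node_states(edge[e, 2]))]
  }
  log(sum(pr))
}

# per-edge transition matrices for a single dN/dS class, matching the
# mixture engine's shared-time-scale convention
oracle_P_list <- function(tree, kappa, omega, pi, scale = 1) {
  Q <- build_rate_matrix(codon_params(kappa, omega, pi))
  rr <- relative_rate(kappa, omega, pi)
  lapply(tree$edge.length * scale * rr, function(t)
    transition_matrix(Q, t, pi))
}

# brute-force branch-site Model A total log-likelihood on a toy alignment
brute_modelA_loglik <- function(aln, tree, mix, scale = 1) {
  pi <- mix$pi
  maps <- list(bg = c(mix$omega0, 1, mix$omega0, 1),
               fg = c(mix$omega0, 1, mix$omega2, mix$omega2))
  w <- c(mix$p0, mix$p1, mix$p2a, mix$p2b)
  fg_child <- tree$edge[foreground_edge(tree), 2]
  Pl <- lapply(1:4, function(cl) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      om <- if (tree$edge[e, 2] == fg_child) maps$fg[cl] else maps$bg[cl]
      Q <- build_rate_matrix(codon_params(mix$kappa, om, pi))
      transition_matrix(Q, tree$edge.length[e] * scale *
                          relative_rate(mix$kappa, om, pi), pi)
    })
  })
  total <- 0
  for (s in seq_len(n_codons(aln))) {
    col <- aln$codons[, s]
    sitelik <- 0
    for (cl in 1:4) {
      if (w[cl] == 0) next
      sitelik <- sitelik +
        w[cl] * exp(brute_site_loglik(tree, col, Pl[[cl]], pi))
    }
    total <- total + log(sitelik)
  }
  total
}

# naive Gotoh affine-gap global alignment score (match/mismatch matrix sub,
# gap of length L costs open + L * extend)
gotoh_score <- function(a, b, sub, open, extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)
  Y <- matrix(NEG, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in 2:(la + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(lb + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(la + 1)) for (j in 2:(lb + 1)) {
    s <- sub[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
  }
  max(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
}

# score an already-aligned pair of rows under the same affine scheme
score_aligned_pair <- function(ra, rb, sub, open, extend) {
  A <- strsplit(ra, "")[[1]]; B <- strsplit(rb, "")[[1]]
  sc <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(A)) {
    if (A[k] == "-" && B[k] == "-") next
    if (A[k] == "-") {
      sc <- sc - extend - (!in_gap_a) * open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (B[k] == "-") {
      sc <- sc - extend - (!in_gap_b) * open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      sc <- sc + sub[A[k], B[k]]
      in_gap_a <- in_gap_b <- FALSE
    }
  }
  sc
}

# hand step-up Benjamini-Hochberg
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# direct-summation BEB oracle: same grid definition as beb_posteriors,
# computed with scalar loops over cells and sites
beb_direct <- function(aln, tree, mle, scale = 1, grid_n = 10) {
  ws <- primsel:::likelihood_workspace(aln, tree, pi = mle$pi)
  mid <- (seq_len(grid_n) - 0.5) / grid_n
  w0g <- mid; w2g <- 1 + 10 * mid
  n <- ws$n_sites
  # per-site class log-likelihood at (w0, w2); cells sharing the same
  # omega pair reuse the same likelihoods (the cell summation stays naive)
  ll_cache <- new.env(parent = emptyenv())
  site_class_ll <- function(w0, w2) {
    k <- paste(w0, w2)
    if (is.null(ll_cache[[k]])) {
      l0 <- primsel:::pattern_loglik(ws, mle$kappa, w0, scale = scale)
      l1 <- primsel:::pattern_loglik(ws, mle$kappa, 1, scale = scale)
      l2a <- primsel:::pattern_loglik(ws, mle$kappa, w0, w2, scale)
      l2b <- primsel:::pattern_loglik(ws, mle$kappa, 1, w2, scale)
      ll_cache[[k]] <- rbind(l0, l1, l2a, l2b)[, ws$pat_map, drop = FALSE]
    }
    ll_cache[[k]]
  }
  cells <- list(); ll <- c()
  idx <- 0
  cell_f <- list(); cell_pos <- list(); cell_ll <- c()
  for (ip0 in mid) for (ip1 in mid) for (i0 in w0g) for (i2 in w2g) {
    p0 <- ip0; p1 <- (1 - ip0) * ip1
    s <- p0 + p1; p2 <- 1 - s
    wts <- c(p0, p1, p2 * p0 / s, p2 * p1 / s)
    cl <- site_class_ll(i0, i2)
    f <- colSums(wts * exp(cl))
    idx <- idx + 1
    cell_f[[idx]] <- f
    cell_pos[[idx]] <- colSums(wts[3:4] * exp(cl[3:4, , drop = FALSE]))
    cell_ll[idx] <- sum(log(f))
  }
  post_cell <- exp(cell_ll - max(cell_ll))
  post_cell <- post_cell / sum(post_cell)
  out <- numeric(n)
  for (k in seq_len(idx)) {
    out <- out + post_cell[k] * cell_pos[[k]] / cell_f[[k]]
  }
  out
}
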