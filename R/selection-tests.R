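# Gene-level tests for episodic positive selection on a foreground branch
# (branch-site Model A LRT; simplified aBSREL-style per-branch test),
# site-level detection (Bayes empirical Bayes posteriors; MEME-style
# per-site mixture test), BH correction and the two-method consensus.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to `stats::p.adjust`), order-preserving
#' with the input indexing.
#'
#' @param pvalues Numeric vector of p-values in `[0,1]`.
#' @return Adjusted q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

.lrt_pvalue <- function(stat, null_dist) {
  stat <- max(stat, 0)
  switch(null_dist,
         chisq1 = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         mixture = if (stat <= 0) 1 else
           0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
         chisq1_2mix = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
           0.5 * stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Branch-site likelihood-ratio test for positive selection
#'
#' Fits the alternative (foreground `omega2 >= 1` free) and null
#' (`omega2 = 1`) branch-site Model A, forms `2 (lnL1 - lnL0)` (clamped at
#' 0) and converts it to a p-value from the asymptotic boundary null, the
#' 50:50 mixture of a point mass at zero and chi-squared(1) (default), or
#' from the more conservative plain chi-squared(1) reference.
#' Branch lengths come from the species tree, rescaled by a rate factor
#' estimated under the one-ratio model when `estimate_scale` is `TRUE`.
#'
#' @param aln A `codon_aln`.
#' @param tree `phylo` tree; marked with [mark_foreground()] beforehand or
#'   via `foreground`.
#' @param foreground Optional foreground label passed to [mark_foreground()].
#' @param gene Gene identifier carried into the result.
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @param estimate_scale Estimate an overall rate scale under M0 first.
#' @param nstarts Optimizer starts per model fit.
#' @param null_dist `"mixture"` (boundary mixture, default) or `"chisq1"`
#'   (conservative).
#' @param kappa `"m0"` (default) fixes kappa at its one-ratio estimate for
#'   the branch-site fits; `"free"` re-estimates it within Model A.
#' @param seed Seed for optimizer multi-starts.
#' @return An `lrt_result` list: gene, lnL0, lnL1, statistic, df, p, and the
#'   two fitted mixtures (`fit0`, `fit1`), scale.
#' @export
branch_site_lrt <- function(aln, tree, foreground = NULL, gene = NA_character_,
                            pi = NULL, estimate_scale = TRUE, nstarts = 3,
                            null_dist = c("mixture", "chisq1"),
                            kappa = c("m0", "free"), seed = 1L) {
  null_dist <- match.arg(null_dist)
  kappa <- match.arg(kappa)
  if (!is.null(foreground)) tree <- mark_foreground(tree, foreground)
  if (is.null(attr(tree, "foreground"))) stop("tree has no foreground mark")
  if (is.null(pi)) pi <- codon_frequencies(aln, "F3x4")
  m0 <- fit_m0(aln, tree, pi = pi, estimate_scale = estimate_scale)
  fix_kappa <- if (kappa == "m0") m0$kappa else NULL
  start <- site_class_mixture(0.45, 0.45, omega0 = min(m0$omega, 0.9),
                              omega2 = 2, kappa = m0$kappa, pi = pi)
  fit0 <- fit_model(aln, tree, "null", pi = pi, scale = m0$scale,
                    nstarts = nstarts, start = start, fix_kappa = fix_kappa,
                    seed = seed)
  # two deterministic warm starts for the alternative: from the null MLE
  # with modest omega2, and a strong-selection start (guards against the
  # omega2/p2 ridge trapping the fit near the null)
  start1 <- fit0$mix
  start1$omega2 <- 2
  fit1 <- fit_model(aln, tree, "alternative", pi = pi, scale = m0$scale,
                    nstarts = nstarts, start = start1, fix_kappa = fix_kappa,
                    seed = seed + 1L)
  start2 <- site_class_mixture(0.8 * fit0$mix$p0, 0.8 * fit0$mix$p1,
                               omega0 = fit0$mix$omega0, omega2 = 8,
                               kappa = fit0$mix$kappa, pi = pi)
  fit1b <- fit_model(aln, tree, "alternative", pi = pi, scale = m0$scale,
                     nstarts = 1, start = start2, fix_kappa = fix_kappa,
                     seed = seed + 2L)
  if (fit1b$lnL > fit1$lnL) fit1 <- fit1b
  # nested models: the alternative can never be worse than the null
  lnL1 <- max(fit1$lnL, fit0$lnL)
  stat <- max(2 * (lnL1 - fit0$lnL), 0)
  structure(list(gene = gene, lnL0 = fit0$lnL, lnL1 = lnL1,
                 statistic = stat, df = 1L,
                 p = .lrt_pvalue(stat, null_dist),
                 fit0 = fit0, fit1 = fit1, scale = m0$scale,
                 method = "branch_site"),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("%s LRT%s: 2dlnL = %.4f, p = %.4g\n", x$method,
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$statistic, x$p))
  invisible(x)
}

# Factory for the per-site log-likelihood of the branch-random-effects model
# used by the aBSREL-style test: background edge e has its own omega_e, the
# foreground edge a 2-class mixture {omega_minus w.p. 1-w, omega_plus w.p.
# w}. Pruning passes are memoized on the parameter values so weight-only
# optimizer steps are free.
.absrel_components <- function(ws, kappa, scale) {
  bmemo <- new_bounded_memo(list(ed = 8L, fg = 12L, cube = 4L,
                                     eP = 64L, ll = 64L))
  memo <- function(k, compute) bmemo(sub("\\|.*", "", k), k, compute)
  ed_of <- function(om) {
    memo(paste0("ed|", format(om, digits = 17)), function() {
      eigen_decompose_Q(build_rate_matrix(codon_params(kappa, om, ws$pi)),
                        ws$pi)
    })
  }
  fg_P <- function(om) {
    memo(paste0("fg|", format(om, digits = 17)), function() {
      ed <- ed_of(om)
      build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                       ws$t[ws$fg_row] * scale *
                         relative_rate(kappa, om, ws$pi))[, , 1]
    })
  }
  shared_cube <- function(om) {
    memo(paste0("cube|", format(om, digits = 17)), function() {
      ed <- ed_of(om)
      build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                       ws$t * scale * relative_rate(kappa, om, ws$pi))
    })
  }
  edge_P <- function(om, e) {
    memo(paste0("eP|", format(om, digits = 17), "|", e), function() {
      ed <- ed_of(om)
      build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                       ws$t[e] * scale *
                         relative_rate(kappa, om, ws$pi))[, , 1]
    })
  }
  pass_shared <- function(om_bg, om_fg) {
    memo(paste0("ll|", format(om_bg, digits = 17), "|",
                format(om_fg, digits = 17)), function() {
      as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, shared_cube(om_bg),
                                  as.integer(ws$fg_row), fg_P(om_fg),
                                  ws$states, ws$pi))
    })
  }
  eval_shared <- function(om_bg, omega_minus, omega_plus, w) {
    mix_logsumexp(rbind(pass_shared(om_bg, omega_minus),
                        pass_shared(om_bg, omega_plus)),
                  c(1 - w, w))
  }
  eval_cube <- function(cube, omega_minus, omega_plus, w) {
    la <- as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube,
                                      as.integer(ws$fg_row),
                                      fg_P(omega_minus), ws$states, ws$pi))
    lb <- as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube,
                                      as.integer(ws$fg_row),
                                      fg_P(omega_plus), ws$states, ws$pi))
    mix_logsumexp(rbind(la, lb), c(1 - w, w))
  }
  list(eval_shared = eval_shared, eval_cube = eval_cube,
       shared_cube = shared_cube, edge_P = edge_P)
}

#' Simplified aBSREL-style branch test
#'
#' A per-branch random-effects test: the foreground branch carries a
#' two-class dN/dS distribution (`omega_minus <= 1` with probability `1 - w`,
#' `omega_plus` with probability `w`), while each background branch gets its
#' own single dN/dS (fitted in a shared stage plus optional per-branch
#' refinement passes). The null constrains `omega_plus <= 1`; the statistic
#' is referred to an equal mixture of chi-squared(1) and chi-squared(2).
#'
#' @inheritParams branch_site_lrt
#' @param refine_passes Number of per-branch coordinate refinement passes for
#'   the background dN/dS values (0 = shared background only).
#' @return An `lrt_result` with fields as in [branch_site_lrt()] plus the
#'   fitted foreground parameters and per-branch background dN/dS.
#' @export
absrel_like_branch_test <- function(aln, tree, foreground = NULL,
                                    gene = NA_character_, pi = NULL,
                                    estimate_scale = TRUE, refine_passes = 1,
                                    seed = 1L) {
  if (!is.null(foreground)) tree <- mark_foreground(tree, foreground)
  if (is.null(attr(tree, "foreground"))) stop("tree has no foreground mark")
  if (is.null(pi)) pi <- codon_frequencies(aln, "F3x4")
  m0 <- fit_m0(aln, tree, pi = pi, estimate_scale = estimate_scale)
  ws <- likelihood_workspace(aln, tree, pi)
  kappa <- m0$kappa; scale <- m0$scale
  ne <- nrow(ws$edge)
  comps <- .absrel_components(ws, kappa, scale)

  fit_one <- function(null) {
    # stage 1: shared background omega + foreground mixture
    nll_shared <- function(x) {
      ob <- exp(x[1]); om <- inv_logit(x[2])
      op <- if (null) inv_logit(x[3]) else exp(x[3])
      w <- inv_logit(x[4])
      -sum(ws$weights * comps$eval_shared(ob, om, op, w))
    }
    x0 <- c(log(max(min(m0$omega, 5), 0.02)), logit(0.5),
            if (null) logit(0.8) else log(2), logit(0.15))
    lo <- c(log(1e-3), -10, if (null) -10 else log(1e-3), -10)
    hi <- c(log(20), 10, if (null) 10 else log(100), 10)
    f1 <- stats::optim(x0, nll_shared, method = "L-BFGS-B", lower = lo,
                       upper = hi, control = .opt_control(200))
    ob <- exp(f1$par[1]); om <- inv_logit(f1$par[2])
    op <- if (null) inv_logit(f1$par[3]) else exp(f1$par[3])
    w <- inv_logit(f1$par[4])
    omega_bg <- rep(ob, ne)
    lnL <- -f1$value
    # stage 2: per-branch background refinement (coordinate descent on a
    # mutable copy of the transition cube)
    if (refine_passes > 0) {
      cube <- comps$shared_cube(ob)
      bg_edges <- setdiff(seq_len(ne), ws$fg_row)
      for (pass in seq_len(refine_passes)) {
        for (e in bg_edges) {
          keep <- cube[, , e]
          obj <- function(lo_w) {
            cube[, , e] <- comps$edge_P(exp(lo_w), e)
            -sum(ws$weights * comps$eval_cube(cube, om, op, w))
          }
          opt <- stats::optimize(obj, c(log(1e-3), log(20)), tol = 0.02)
          if (-opt$objective > lnL) {
            omega_bg[e] <- exp(opt$minimum)
            cube[, , e] <- comps$edge_P(omega_bg[e], e)
            lnL <- -opt$objective
          } else {
            cube[, , e] <- keep
          }
        }
      }
    }
    list(lnL = lnL, omega_bg = omega_bg, omega_minus = om, omega_plus = op,
         w = w)
  }

  fit0 <- fit_one(null = TRUE)
  fit1 <- fit_one(null = FALSE)
  lnL1 <- max(fit1$lnL, fit0$lnL)
  stat <- max(2 * (lnL1 - fit0$lnL), 0)
  structure(list(gene = gene, lnL0 = fit0$lnL, lnL1 = lnL1,
                 statistic = stat, df = NA_integer_,
                 p = .lrt_pvalue(stat, "chisq1_2mix"),
                 fit0 = fit0, fit1 = fit1, scale = m0$scale,
                 method = "absrel_like"),
            class = "lrt_result")
}

#' Bayes empirical Bayes posteriors for positively selected sites
#'
#' Grid-based empirical Bayes over `(p0, p1, omega0, omega2)` with a
#' 10-point uniform grid per dimension and equal prior mass per cell (the
#' `(p0, p1)` grid is mapped onto the simplex via
#' `p1 = (1 - p0) * p1grid`). `kappa`, codon frequencies and branch lengths
#' are held at their estimates. Returns the per-site posterior probability
#' of the positively selected classes (2a + 2b).
#'
#' @param aln A `codon_aln`.
#' @param tree Foreground-marked tree.
#' @param mle A fitted `site_class_mixture` (kappa and pi are taken from it).
#' @param scale Branch-length scale used during fitting.
#' @param grid_n Grid points per dimension (default 10).
#' @param flag_threshold Posterior at or above which a site is flagged.
#' @return data.frame: site, beb_posterior, flagged; attribute
#'   `"class_posterior"` holds the 4 x n_sites full class-posterior matrix.
#' @export
beb_posteriors <- function(aln, tree, mle, scale = 1, grid_n = 10,
                           flag_threshold = 0.95) {
  if (grid_n < 2) stop("degenerate grid")
  ws <- likelihood_workspace(aln, tree, pi = mle$pi)
  if (ws$fg_row == 0L) stop("tree has no foreground mark")
  mid <- (seq_len(grid_n) - 0.5) / grid_n
  w0_grid <- mid                   # omega0 in [0,1]
  w2_grid <- 1 + 10 * mid          # omega2 in [1,11]
  kappa <- mle$kappa

  # per-site log-likelihood of each class at each grid omega
  L0 <- vapply(w0_grid, function(w0)
    pattern_loglik(ws, kappa, w0, scale = scale), numeric(ncol(ws$states)))
  L1 <- pattern_loglik(ws, kappa, 1, scale = scale)
  L2b <- vapply(w2_grid, function(w2)
    pattern_loglik(ws, kappa, 1, w2, scale), numeric(ncol(ws$states)))
  L2a <- array(0, c(ncol(ws$states), grid_n, grid_n))
  for (i in seq_len(grid_n)) {
    L2a[, i, ] <- vapply(w2_grid, function(w2)
      pattern_loglik(ws, kappa, w0_grid[i], w2, scale),
      numeric(ncol(ws$states)))
  }

  npat <- ncol(ws$states)
  m <- pmax(apply(L0, 1, max), L1, apply(L2b, 1, max),
            apply(L2a, 1, max))
  e0 <- exp(L0 - m); e1 <- exp(L1 - m); e2b <- exp(L2b - m)
  e2a <- exp(L2a - as.vector(m))

  cells <- expand.grid(ip0 = mid, ip1 = mid, iw0 = seq_len(grid_n),
                       iw2 = seq_len(grid_n))
  p0 <- cells$ip0
  p1 <- (1 - cells$ip0) * cells$ip1
  s <- p0 + p1; p2 <- 1 - s
  p2a <- p2 * p0 / s; p2b <- p2 * p1 / s

  ncell <- nrow(cells)
  cell_parts <- function(k) {
    i0 <- cells$iw0[k]; i2 <- cells$iw2[k]
    cbind(p0[k] * e0[, i0], p1[k] * e1,
          p2a[k] * e2a[, i0, i2], p2b[k] * e2b[, i2])
  }
  # pass 1: posterior mass of each grid cell given the whole alignment
  cell_loglik <- vapply(seq_len(ncell), function(k) {
    sum(ws$weights * (log(rowSums(cell_parts(k))) + m))
  }, numeric(1))
  cell_post <- exp(cell_loglik - max(cell_loglik))
  cell_post <- cell_post / sum(cell_post)
  # pass 2: accumulate site-class posteriors averaged over cells
  cls_post <- matrix(0, npat, 4)
  for (k in seq_len(ncell)) {
    if (cell_post[k] < 1e-16) next
    parts <- cell_parts(k)
    cls_post <- cls_post + cell_post[k] * parts / rowSums(parts)
  }
  post <- (cls_post[, 3] + cls_post[, 4])[ws$pat_map]
  out <- data.frame(site = seq_along(post), beb_posterior = post,
                    flagged = post >= flag_threshold)
  attr(out, "class_posterior") <- t(cls_post[ws$pat_map, , drop = FALSE])
  out
}

#' MEME-style per-site test for episodic selection
#'
#' Per site, fits a two-class model in which all branches share a purifying
#' rate `omega_minus <= 1` while the foreground branch draws, with
#' probability `w`, an unconstrained rate `omega_plus`; the null constrains
#' `omega_plus <= 1`. Because the single-site likelihood is log-linear in
#' `w`, its maximum sits at a boundary (`w` of 0 or 1), so the fit profiles
#' deterministically over an `(omega_minus, omega_plus)` grid with
#' per-gene precomputed spectral decompositions. The per-site LRT statistic
#' is referred to an equal mixture of chi-squared(1) and chi-squared(2) (an
#' approximation to the asymptotics of such boundary mixtures, validated by
#' simulation). Invariant and all-missing sites short-circuit to p = 1.
#'
#' @inheritParams branch_site_lrt
#' @param alpha Flagging threshold on the per-site p-value.
#' @param kappa,scale Optional fixed values (otherwise estimated under M0).
#' @param omega_minus_grid,omega_plus_grid Profile grids; the plus grid must
#'   contain values on both sides of 1 so the null (`omega_plus <= 1`) is a
#'   restriction of the alternative.
#' @return data.frame: site, statistic, p, flagged, note.
#' @export
meme_like_site_test <- function(aln, tree, foreground = NULL, pi = NULL,
                                alpha = 0.05, kappa = NULL, scale = NULL,
                                omega_minus_grid = c(0, 0.02, 0.1, 0.25,
                                                     0.5, 0.75, 1),
                                omega_plus_grid = c(0, 0.02, 0.1, 0.25, 0.5,
                                                    0.75, 1, 1.5, 2, 3, 5,
                                                    8, 15, 30)) {
  if (!is.null(foreground)) tree <- mark_foreground(tree, foreground)
  if (is.null(attr(tree, "foreground"))) stop("tree has no foreground mark")
  if (is.null(pi)) pi <- codon_frequencies(aln, "F3x4")
  if (is.null(kappa) || is.null(scale)) {
    m0 <- fit_m0(aln, tree, pi = pi)
    if (is.null(kappa)) kappa <- m0$kappa
    if (is.null(scale)) scale <- m0$scale
  }
  ws <- likelihood_workspace(aln, tree, pi)
  tsc <- ws$t * scale
  grid_all <- sort(unique(c(omega_minus_grid, omega_plus_grid)))
  eds <- lapply(grid_all, function(om) {
    ed <- eigen_decompose_Q(build_rate_matrix(codon_params(kappa, om, pi)),
                            pi)
    ed$lambda <- ed$lambda * relative_rate(kappa, om, pi)
    ed
  })
  names(eds) <- vapply(grid_all, format, "", digits = 17)
  ed_of <- function(om) eds[[format(om, digits = 17)]]

  # profile the site log-likelihood over the grid; w is at a boundary, so
  # each (omega_minus, omega_plus) cell contributes max(la, lb)
  site_profile <- function(states) {
    best_alt <- -Inf; best_null <- -Inf
    for (om in omega_minus_grid) {
      edm <- ed_of(om)
      for (op in omega_plus_grid) {
        edp <- ed_of(op)
        ll <- prune_col_two_cpp(ws$edge, ws$n_tip, edm$A, edm$B, edm$lambda,
                                edp$A, edp$B, edp$lambda, tsc,
                                as.integer(ws$fg_row), states, pi)
        cell <- max(ll)
        if (cell > best_alt) best_alt <- cell
        if (op <= 1 && cell > best_null) best_null <- cell
      }
    }
    c(null = best_null, alt = best_alt)
  }

  nsite <- ws$n_sites
  pat_stat <- rep(NA_real_, ncol(ws$states))
  pat_note <- rep("", ncol(ws$states))
  for (k in seq_len(ncol(ws$states))) {
    st <- ws$states[, k]
    obs <- unique(st[st > 0])
    if (length(obs) == 0L) {
      pat_stat[k] <- 0; pat_note[k] <- "no data"
    } else if (length(obs) == 1L) {
      pat_stat[k] <- 0; pat_note[k] <- "invariant"
    } else {
      pr <- site_profile(st)
      pat_stat[k] <- max(2 * (pr["alt"] - pr["null"]), 0)
    }
  }
  stat <- pat_stat[ws$pat_map]
  note <- pat_note[ws$pat_map]
  p <- vapply(stat, .lrt_pvalue, numeric(1), null_dist = "chisq1_2mix")
  p[stat <= 0] <- 1
  data.frame(site = seq_len(nsite), statistic = stat, p = p,
             flagged = p < alpha, note = note)
}

#' Two-method consensus for candidate genes and sites
#'
#' Candidate genes are those with `p < alpha` under both gene-level methods
#' (raw p-values by default, with BH q-values reported alongside); candidate
#' sites, within candidate genes, are the intersection of the BEB-flagged
#' and MEME-flagged site sets.
#'
#' @param genes_a,genes_b data.frames with columns `gene`, `p` (one row per
#'   gene, same gene universe).
#' @param sites_a,sites_b data.frames with columns `gene`, `site`, `flagged`.
#' @param alpha Gene-level significance threshold.
#' @return List with `genes` (gene, p_a, p_b, q_a, q_b) and `sites`
#'   (gene, site with both-method evidence).
#' @export
consensus <- function(genes_a, genes_b, sites_a = NULL, sites_b = NULL,
                      alpha = 0.05) {
  if (!setequal(genes_a$gene, genes_b$gene)) {
    stop("gene universes differ between methods")
  }
  gb <- genes_b[match(genes_a$gene, genes_b$gene), ]
  tab <- data.frame(gene = genes_a$gene, p_a = genes_a$p, p_b = gb$p,
                    q_a = bh_adjust(genes_a$p), q_b = bh_adjust(gb$p))
  cand <- tab[tab$p_a < alpha & tab$p_b < alpha, , drop = FALSE]
  sites <- NULL
  if (!is.null(sites_a) && !is.null(sites_b)) {
    sa <- sites_a[sites_a$flagged & sites_a$gene %in% cand$gene, ,
                  drop = FALSE]
    sb <- sites_b[sites_b$flagged & sites_b$gene %in% cand$gene, ,
                  drop = FALSE]
    key_a <- paste(sa$gene, sa$site)
    key_b <- paste(sb$gene, sb$site)
    both <- intersect(key_a, key_b)
    sites <- sa[key_a %in% both, c("gene", "site"), drop = FALSE]
    rownames(sites) <- NULL
  }
  list(genes = cand, sites = sites, all_genes = tab)
}
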