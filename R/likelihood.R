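#' Branch-site Model A site-class mixture
#'
#' Four site classes: class 0 (purifying, omega0 on all branches), class 1
#' (neutral, omega = 1), and classes 2a/2b which behave like classes 0/1 on
#' background branches but take `omega2` on the foreground branch. The
#' proportions of 2a and 2b are derived from `p0`, `p1` in the usual
#' proportional way: `p2a = (1-p0-p1) p0/(p0+p1)`, `p2b = (1-p0-p1) p1/(p0+p1)`.
#'
#' @param p0,p1 Class proportions in `[0,1]` with `p0 + p1 <= 1` and
#'   `p0 + p1 > 0`.
#' @param omega0 Purifying dN/dS in `[0,1]`.
#' @param omega2 Foreground dN/dS of the selected classes, `>= 1` in the
#'   alternative model, `= 1` in the null.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (length 61).
#' @return Object of class `site_class_mixture` with derived `p2a`, `p2b`.
#' @export
site_class_mixture <- function(p0, p1, omega0, omega2 = 1, kappa = 2,
                               pi = rep(1 / 61, 61)) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12, p0 + p1 > 0,
            omega0 >= 0, omega0 <= 1, omega2 >= 0, kappa > 0,
            length(pi) == 61)
  s <- min(p0 + p1, 1)
  p2 <- 1 - s
  structure(list(p0 = p0, p1 = p1,
                 p2a = p2 * p0 / s, p2b = p2 * p1 / s,
                 omega0 = omega0, omega2 = omega2,
                 kappa = kappa, pi = pi / sum(pi)),
            class = "site_class_mixture")
}

#' @export
print.site_class_mixture <- function(x, ...) {
  cat(sprintf(
    "site-class mixture: p0=%.3f p1=%.3f p2a=%.3f p2b=%.3f w0=%.3f w2=%.3f kappa=%.3f\n",
    x$p0, x$p1, x$p2a, x$p2b, x$omega0, x$omega2, x$kappa))
  invisible(x)
}

mixture_weights <- function(mix) c(mix$p0, mix$p1, mix$p2a, mix$p2b)

# class -> omega maps; background {w0, 1, w0, 1}, foreground {w0, 1, w2, w2}
mixture_omega_maps <- function(mix) {
  list(background = c(mix$omega0, 1, mix$omega0, 1),
       foreground = c(mix$omega0, 1, mix$omega2, mix$omega2))
}

# Precomputed per-(alignment, tree) quantities reused across optimizer calls.
likelihood_workspace <- function(aln, tree, pi = NULL) {
  po <- tree_postorder(tree)
  if (!all(po$labels %in% aln$taxa)) stop("tree tips missing from alignment")
  states <- aln_states(aln, po$labels)
  pat <- compress_patterns(states)
  fg_row <- 0L
  if (!is.null(attr(tree, "foreground"))) {
    fg_child <- tree$edge[foreground_edge(tree), 2]
    fg_row <- which(po$edge[, 2] == fg_child)
  }
  if (is.null(pi)) pi <- codon_frequencies(aln, "F3x4")
  list(edge = po$edge, n_tip = po$n_tip, t = po$lengths, fg_row = fg_row,
       states = pat$states, weights = pat$weights, pat_map = pat$map,
       pi = pi, n_sites = ncol(states))
}

# per-pattern log-likelihood for a single-omega regime on all branches,
# optionally overriding the foreground branch with another omega
pattern_loglik <- function(ws, kappa, omega_bg, omega_fg = omega_bg,
                           scale = 1) {
  Qb <- build_rate_matrix(codon_params(kappa, omega_bg, ws$pi))
  edb <- eigen_decompose_Q(Qb, ws$pi)
  rb <- relative_rate(kappa, omega_bg, ws$pi)
  Pcube <- build_P_cube_cpp(edb$A, edb$B, edb$lambda, ws$t * scale * rb)
  fg <- 0L
  Pfg <- matrix(0, 1, 1)
  if (omega_fg != omega_bg) {
    if (ws$fg_row == 0L) stop("tree has no foreground mark")
    Qf <- build_rate_matrix(codon_params(kappa, omega_fg, ws$pi))
    edf <- eigen_decompose_Q(Qf, ws$pi)
    rf <- relative_rate(kappa, omega_fg, ws$pi)
    Pfg <- build_P_cube_cpp(edf$A, edf$B, edf$lambda,
                            ws$t[ws$fg_row] * scale * rf)[, , 1]
    fg <- as.integer(ws$fg_row)
  }
  as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, Pcube, fg, Pfg,
                              ws$states, ws$pi))
}

# 4 x npat matrix of per-class per-pattern log-likelihoods under Model A
modelA_class_logliks <- function(ws, mix, scale = 1) {
  if (ws$fg_row == 0L) stop("tree has no foreground mark")
  omegas <- unique(c(mix$omega0, 1, mix$omega2))
  eds <- lapply(omegas, function(w) {
    Q <- build_rate_matrix(codon_params(mix$kappa, w, ws$pi))
    eigen_decompose_Q(Q, ws$pi)
  })
  names(eds) <- as.character(omegas)
  cube_for <- function(w) {
    ed <- eds[[as.character(w)]]
    build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                     ws$t * scale * relative_rate(mix$kappa, w, ws$pi))
  }
  cube0 <- cube_for(mix$omega0)
  cube1 <- if (mix$omega0 == 1) cube0 else cube_for(1)
  ed2 <- eds[[as.character(mix$omega2)]]
  Pfg2 <- build_P_cube_cpp(ed2$A, ed2$B, ed2$lambda,
                           ws$t[ws$fg_row] * scale *
                             relative_rate(mix$kappa, mix$omega2,
                                           ws$pi))[, , 1]
  fg <- as.integer(ws$fg_row)
  rbind(
    as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube0, 0L,
                                matrix(0, 1, 1), ws$states, ws$pi)),
    as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube1, 0L,
                                matrix(0, 1, 1), ws$states, ws$pi)),
    as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube0, fg, Pfg2,
                                ws$states, ws$pi)),
    as.numeric(prune_loglik_cpp(ws$edge, ws$n_tip, cube1, fg, Pfg2,
                                ws$states, ws$pi)))
}

# log(sum_c w_c exp(l_c)) column-wise, numerically stable
mix_logsumexp <- function(logliks, weights) {
  keep <- weights > 0
  ll <- logliks[keep, , drop = FALSE] + log(weights[keep])
  m <- apply(ll, 2, max)
  m + log(colSums(exp(sweep(ll, 2, m))))
}

#' Pruning log-likelihood of a single alignment column
#'
#' Felsenstein pruning with per-node scaling. Missing states (gap or `N`
#' codons) contribute all-ones partial vectors; a column that is missing in
#' every taxon therefore has log-likelihood 0.
#'
#' @param tree `phylo` tree.
#' @param column Character vector of codons (or `NA` for missing), named by
#'   taxon or ordered as `tree$tip.label`.
#' @param P List of 61 x 61 transition matrices, one per row of `tree$edge`.
#' @param pi Root codon frequencies.
#' @return Log-likelihood (scalar).
#' @export
site_log_likelihood <- function(tree, column, P, pi) {
  if (length(P) != nrow(tree$edge)) stop("need one P matrix per edge")
  if (!is.null(names(column))) column <- column[tree$tip.label]
  if (length(column) != ape::Ntip(tree)) stop("column width mismatch")
  po <- tree_postorder(tree)
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  cube <- array(unlist(P[ord]), dim = c(61, 61, length(P)))
  states <- matrix(codon_index(column)[match(po$labels, tree$tip.label)],
                   ncol = 1)
  states[is.na(states)] <- 0L
  as.numeric(prune_loglik_cpp(po$edge, po$n_tip, cube, 0L,
                              matrix(0, 1, 1), states, pi))
}

#' Branch-site Model A total log-likelihood
#'
#' Per site, the likelihood is the mixture over the four site classes of the
#' pruning likelihood computed with that class's branch-specific dN/dS map;
#' the total is the sum of per-site logs.
#'
#' @param aln A `codon_aln`.
#' @param tree Foreground-marked `phylo` tree with branch lengths.
#' @param mix A [site_class_mixture()].
#' @param scale Optional overall branch-length multiplier.
#' @return Scalar total log-likelihood, with per-site values in attribute
#'   `"site_loglik"`.
#' @export
model_A_loglik <- function(aln, tree, mix, scale = 1) {
  ws <- likelihood_workspace(aln, tree, pi = mix$pi)
  cls <- modelA_class_logliks(ws, mix, scale)
  site_pat <- mix_logsumexp(cls, mixture_weights(mix))
  total <- sum(ws$weights * site_pat)
  attr(total, "site_loglik") <- site_pat[ws$pat_map]
  total
}

#' Dump model diagnostics as TSV files
#'
#' Writes the rate matrix, a transition matrix at a given branch length and
#' the per-site log-likelihoods of a single-ratio model, for debugging.
#'
#' @param aln A `codon_aln`.
#' @param tree `phylo` tree with branch lengths.
#' @param params A [codon_params()].
#' @param t Branch length for the transition-matrix dump.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
dump_model_diagnostics <- function(aln, tree, params, t = 0.1,
                                   out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Q <- build_rate_matrix(params)
  P <- transition_matrix(Q, t, params$pi)
  dimnames(P) <- dimnames(Q)
  ws <- likelihood_workspace(aln, tree, params$pi)
  site_ll <- pattern_loglik(ws, params$kappa, params$omega)[ws$pat_map]
  paths <- list(Q = file.path(out_dir, "rate_matrix.tsv"),
                P = file.path(out_dir, "transition_matrix.tsv"),
                sites = file.path(out_dir, "site_loglik.tsv"))
  utils::write.table(Q, paths$Q, sep = "\t", quote = FALSE)
  utils::write.table(P, paths$P, sep = "\t", quote = FALSE)
  utils::write.table(data.frame(site = seq_along(site_ll),
                                loglik = site_ll),
                     paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
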