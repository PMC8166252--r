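# Maximum-likelihood fitting of codon models. Parameters are optimized on
# transformed scales (log kappa, logit proportions, logit omega0,
# log(omega2 - 1)) with box constraints, by L-BFGS-B. Branch lengths are
# taken from the species tree and held fixed, except for an optional single
# rate scale estimated under the one-ratio (M0) model.
#
# The Model A objective is assembled from four per-class pruning components
# that are memoized on their parameter values: finite-difference gradient
# steps on the mixture proportions then reuse every pruning pass, and steps
# on one omega only recompute the classes that depend on it.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

.opt_control <- function(maxit = 500) {
  # factr ~ 4.5e7 corresponds to a relative lnL tolerance of about 1e-8
  list(maxit = maxit, factr = 4.5e7)
}

#' Fit the one-ratio (M0) codon model
#'
#' Optimizes a single dN/dS, kappa and an overall branch-length scale on a
#' fixed-topology tree. Used to set the per-gene rate scale (and kappa) for
#' the branch-site fits.
#'
#' @param aln A `codon_aln`.
#' @param tree `phylo` tree with branch lengths.
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @param estimate_scale Estimate the overall scale (default) or hold it at 1.
#' @return List with `kappa`, `omega`, `scale`, `lnL`, `convergence`.
#' @export
fit_m0 <- function(aln, tree, pi = NULL, estimate_scale = TRUE) {
  ws <- likelihood_workspace(aln, tree, pi)
  nll <- function(x) {
    kappa <- exp(x[1]); omega <- exp(x[2])
    scale <- if (estimate_scale) exp(x[3]) else 1
    -sum(ws$weights * pattern_loglik(ws, kappa, omega, scale = scale))
  }
  x0 <- c(log(2), log(0.3), if (estimate_scale) 0)
  lower <- c(log(0.05), log(1e-4), if (estimate_scale) log(0.02))
  upper <- c(log(50), log(20), if (estimate_scale) log(50))
  fit <- stats::optim(x0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = .opt_control())
  list(kappa = exp(fit$par[1]), omega = exp(fit$par[2]),
       scale = if (estimate_scale) exp(fit$par[3]) else 1,
       lnL = -fit$value, convergence = fit$convergence)
}

# Bounded memo: a FIFO cache per entry kind, so large cached objects
# (transition cubes, stored pruning passes) cannot accumulate across the
# many parameter values an optimizer visits.
new_bounded_memo <- function(capacity) {
  store <- new.env(parent = emptyenv())
  function(kind, k, compute) {
    slot <- store[[kind]]
    if (is.null(slot)) slot <- list(keys = character(0), values = list())
    hit <- match(k, slot$keys)
    if (!is.na(hit)) return(slot$values[[hit]])
    v <- compute()
    cap <- capacity[[kind]]
    if (is.null(cap)) cap <- 16L
    if (length(slot$keys) >= cap) {
      slot$keys <- slot$keys[-1]
      slot$values <- slot$values[-1]
    }
    slot$keys <- c(slot$keys, k)
    slot$values <- c(slot$values, list(v))
    store[[kind]] <- slot
    v
  }
}

# Memoized per-class Model A pattern log-likelihood components.
# Classes: l0(kappa, w0), l1(kappa), l2a(kappa, w0, w2), l2b(kappa, w2).
.modelA_components <- function(ws, scale) {
  bmemo <- new_bounded_memo(list(ed = 8L, cube = 4L, fg = 12L, base = 3L,
                                 ll = 64L))
  key <- function(...) paste(format(c(...), digits = 17), collapse = "|")
  memo <- function(k, compute) {
    kind <- sub("\\|.*", "", k)
    bmemo(kind, k, compute)
  }
  ed_of <- function(kappa, om) {
    memo(key("ed", kappa, om), function() {
      eigen_decompose_Q(
        build_rate_matrix(codon_params(kappa, om, ws$pi)), ws$pi)
    })
  }
  cube_of <- function(kappa, om) {
    memo(key("cube", kappa, om), function() {
      ed <- ed_of(kappa, om)
      build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                       ws$t * scale * relative_rate(kappa, om, ws$pi))
    })
  }
  fg_slice <- function(kappa, om) {
    memo(key("fg", kappa, om), function() {
      ed <- ed_of(kappa, om)
      build_P_cube_cpp(ed$A, ed$B, ed$lambda,
                       ws$t[ws$fg_row] * scale *
                         relative_rate(kappa, om, ws$pi))[, , 1]
    })
  }
  base_pass <- function(kappa, om_bg) {
    # full pruning with stored partials, reused by foreground overrides
    memo(key("base", kappa, om_bg), function() {
      prune_loglik_store_cpp(ws$edge, ws$n_tip, cube_of(kappa, om_bg),
                             0L, matrix(0, 1, 1), ws$states, ws$pi)
    })
  }
  pass <- function(kappa, om_bg, om_fg) {
    memo(key("ll", kappa, om_bg, om_fg), function() {
      st <- base_pass(kappa, om_bg)
      if (om_fg == om_bg) {
        as.numeric(st$loglik)
      } else {
        # only the foreground-to-root path is recomputed
        as.numeric(prune_fg_update_cpp(ws$edge, ws$n_tip,
                                       cube_of(kappa, om_bg),
                                       as.integer(ws$fg_row),
                                       fg_slice(kappa, om_fg),
                                       ws$states, ws$pi,
                                       st$partial, st$logscale))
      }
    })
  }
  function(mix) {
    rbind(pass(mix$kappa, mix$omega0, mix$omega0),
          pass(mix$kappa, 1, 1),
          pass(mix$kappa, mix$omega0, mix$omega2),
          pass(mix$kappa, 1, mix$omega2))
  }
}

# pack/unpack Model A parameters; the null model drops the omega2
# coordinate and a fixed kappa drops the kappa coordinate
.modelA_pack <- function(p0, p1, omega0, omega2, kappa, null, fix_kappa) {
  s <- min(max(p0 + p1, 1e-6), 1 - 1e-6)
  r <- min(max(p0 / (p0 + p1), 1e-6), 1 - 1e-6)
  c(logit(s), logit(r), logit(min(max(omega0, 1e-6), 1 - 1e-6)),
    if (is.null(fix_kappa)) log(max(kappa, 0.051)),
    if (!null) log(max(omega2 - 1, 1e-7)))
}

.modelA_unpack <- function(x, pi, null, fix_kappa) {
  s <- inv_logit(x[1]); r <- inv_logit(x[2])
  kappa <- if (is.null(fix_kappa)) exp(x[4]) else fix_kappa
  i2 <- if (is.null(fix_kappa)) 5L else 4L
  site_class_mixture(p0 = s * r, p1 = s * (1 - r),
                     omega0 = inv_logit(x[3]),
                     omega2 = if (null) 1 else 1 + exp(x[i2]),
                     kappa = kappa, pi = pi)
}

#' Fit the branch-site Model A by maximum likelihood
#'
#' Fits the null (`omega2 = 1`) or alternative (`omega2 >= 1` free) model
#' with bounded quasi-Newton optimization over transformed parameters and
#' seeded multi-start. Branch lengths come from the tree (times `scale`).
#'
#' @param aln A `codon_aln`.
#' @param tree Foreground-marked `phylo` tree.
#' @param model `"null"` or `"alternative"`.
#' @param pi Codon frequencies; default F3x4.
#' @param scale Fixed branch-length multiplier (e.g. from [fit_m0()]).
#' @param nstarts Number of optimizer starts (default 3).
#' @param start Optional `site_class_mixture` used as the first start.
#' @param fix_kappa Optional numeric: hold kappa at this value instead of
#'   estimating it.
#' @param seed Seed for the jittered extra starts.
#' @return List with `mix` (MLE as a `site_class_mixture`), `lnL`,
#'   `convergence` (0 = converged), `nstarts`.
#' @export
fit_model <- function(aln, tree, model = c("alternative", "null"), pi = NULL,
                      scale = 1, nstarts = 3, start = NULL, fix_kappa = NULL,
                      seed = 1L) {
  model <- match.arg(model)
  null <- model == "null"
  ws <- likelihood_workspace(aln, tree, pi)
  if (ws$fg_row == 0L) stop("tree has no foreground mark")
  components <- .modelA_components(ws, scale)
  nll <- function(x) {
    mix <- .modelA_unpack(x, ws$pi, null, fix_kappa)
    -sum(ws$weights * mix_logsumexp(components(mix), mixture_weights(mix)))
  }
  npar <- 3L + is.null(fix_kappa) + !null
  lower <- c(-12, -12, -12, if (is.null(fix_kappa)) log(0.05), if (!null) -15)
  upper <- c(12, 12, 12, if (is.null(fix_kappa)) log(50), if (!null) log(500))
  starts <- list()
  starts[[1]] <- if (is.null(start)) {
    .modelA_pack(0.45, 0.45, 0.1, 2, 2, null, fix_kappa)
  } else {
    .modelA_pack(start$p0, start$p1, start$omega0,
                 max(start$omega2, 1 + 1e-6), start$kappa, null, fix_kappa)
  }
  if (nstarts > 1) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    for (k in seq_len(nstarts - 1)) {
      starts[[k + 1]] <- pmin(pmax(starts[[1]] + stats::rnorm(npar, 0, 1.2),
                                   lower), upper)
    }
  }
  best <- NULL
  for (x0 in starts) {
    fit <- tryCatch(
      stats::optim(x0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = .opt_control()),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Model A optimization failed to converge")
  list(mix = .modelA_unpack(best$par, ws$pi, null, fix_kappa),
       lnL = -best$value,
       convergence = best$convergence, nstarts = length(starts))
}

# save/restore the RNG state so fitting never perturbs user seeds
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
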