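// Numerical core: Felsenstein pruning over the 61 sense-codon states with
// per-node scaling, plus helpers to build transition-probability cubes from
// a symmetrized eigen-decomposition. Trees arrive as postorder edge matrices
// (children before parents), 1-based node ids, tips 1..n_tip.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build P(t_e) = A * diag(exp(lambda * t_e)) * B for every edge.
// [[Rcpp::export]]
arma::cube build_P_cube_cpp(const arma::mat& A, const arma::mat& B,
                            const arma::vec& lambda, const arma::vec& t) {
  const uword n = A.n_rows, ne = t.n_elem;
  cube P(n, n, ne);
  for (uword e = 0; e < ne; ++e) {
    mat M = B;
    M.each_col() %= exp(lambda * t(e));
    P.slice(e) = A * M;
    P.slice(e).transform([](double x) { return x < 0 ? 0.0 : x; });
    // renormalise rows (guards tiny eigen round-off)
    vec rs = sum(P.slice(e), 1);
    P.slice(e).each_col() /= rs;
  }
  return P;
}

// Per-pattern log-likelihoods by pruning. P is a 61x61xnedge cube aligned
// with the postorder edge matrix; if fg_edge > 0 (1-based row index into
// edge), that edge uses P_fg instead of its slice. tip_states is
// n_tip x npat with 1-based codon states, 0 = missing.
// [[Rcpp::export]]
arma::vec prune_loglik_cpp(const arma::imat& edge, int n_tip,
                           const arma::cube& P, int fg_edge,
                           const arma::mat& P_fg,
                           const arma::imat& tip_states,
                           const arma::vec& pi) {
  const uword ne = edge.n_rows;
  const uword npat = tip_states.n_cols;
  const uword ns = pi.n_elem;
  const int n_node = edge.max();

  std::vector<mat> partial(n_node + 1);
  std::vector<rowvec> logscale(n_node + 1);
  std::vector<bool> seen(n_node + 1, false);

  mat msg(ns, npat);
  for (uword e = 0; e < ne; ++e) {
    const int child = edge(e, 1), parent = edge(e, 0);
    const mat& Pe = ((int)(e + 1) == fg_edge) ? P_fg : P.slice(e);
    rowvec child_scale;
    if (child <= n_tip) {
      for (uword s = 0; s < npat; ++s) {
        const int st = tip_states(child - 1, s);
        if (st > 0) msg.col(s) = Pe.col(st - 1);
        else msg.col(s).ones();
      }
    } else {
      msg = Pe * partial[child];
      child_scale = logscale[child];
      partial[child].reset();
    }
    if (!seen[parent]) {
      partial[parent] = msg;
      logscale[parent] = child_scale.n_elem ? child_scale
                                            : rowvec(npat, fill::zeros);
      seen[parent] = true;
    } else {
      partial[parent] %= msg;
      if (child_scale.n_elem) logscale[parent] += child_scale;
    }
    // rescale parent partials to avoid underflow
    rowvec mx = max(partial[parent], 0);
    for (uword s = 0; s < npat; ++s) {
      if (mx(s) > 0 && (mx(s) < 1e-40 || mx(s) > 1e40)) {
        partial[parent].col(s) /= mx(s);
        logscale[parent](s) += std::log(mx(s));
      }
    }
  }

  const int root = edge(ne - 1, 0);
  vec out(npat);
  for (uword s = 0; s < npat; ++s) {
    const double L = dot(pi, partial[root].col(s));
    out(s) = std::log(L) + logscale[root](s);
  }
  return out;
}

// Fast single-column pruning for per-site tests: two substitution regimes
// given by eigen factors (A,B,lambda); every edge uses regime 1 except the
// foreground edge in the second returned pass, which uses regime 2.
// Returns (logL_all_regime1, logL_fg_regime2).
// [[Rcpp::export]]
arma::vec prune_col_two_cpp(const arma::imat& edge, int n_tip,
                            const arma::mat& A1, const arma::mat& B1,
                            const arma::vec& lam1, const arma::mat& A2,
                            const arma::mat& B2, const arma::vec& lam2,
                            const arma::vec& t, int fg_edge,
                            const arma::ivec& states, const arma::vec& pi) {
  const uword ne = edge.n_rows;
  const uword ns = pi.n_elem;
  const int n_node = edge.max();
  vec out(2);

  for (int pass = 0; pass < 2; ++pass) {
    std::vector<vec> partial(n_node + 1);
    std::vector<double> logscale(n_node + 1, 0.0);
    std::vector<bool> seen(n_node + 1, false);
    for (uword e = 0; e < ne; ++e) {
      const int child = edge(e, 1), parent = edge(e, 0);
      const bool fg2 = (pass == 1) && ((int)(e + 1) == fg_edge);
      const mat& A = fg2 ? A2 : A1;
      const mat& B = fg2 ? B2 : B1;
      const vec& lam = fg2 ? lam2 : lam1;
      vec msg(ns);
      double child_scale = 0.0;
      if (child <= n_tip) {
        const int st = states(child - 1);
        if (st > 0) {
          vec w = B.col(st - 1) % exp(lam * t(e));
          msg = A * w;
        } else {
          msg.ones();
        }
      } else {
        vec w = (B * partial[child]) % exp(lam * t(e));
        msg = A * w;
        child_scale = logscale[child];
      }
      msg.transform([](double x) { return x < 0 ? 0.0 : x; });
      if (!seen[parent]) {
        partial[parent] = msg;
        logscale[parent] = child_scale;
        seen[parent] = true;
      } else {
        partial[parent] %= msg;
        logscale[parent] += child_scale;
      }
      const double mx = partial[parent].max();
      if (mx > 0 && (mx < 1e-40 || mx > 1e40)) {
        partial[parent] /= mx;
        logscale[parent] += std::log(mx);
      }
    }
    const int root = edge(ne - 1, 0);
    out(pass) = std::log(dot(pi, partial[root])) + logscale[root];
  }
  return out;
}

// Full pruning pass that additionally returns the per-node partials and
// log-scales, so a later foreground-only override can update just the
// root path. Partials are stored for internal nodes (id > n_tip).
// [[Rcpp::export]]
Rcpp::List prune_loglik_store_cpp(const arma::imat& edge, int n_tip,
                                  const arma::cube& P, int fg_edge,
                                  const arma::mat& P_fg,
                                  const arma::imat& tip_states,
                                  const arma::vec& pi) {
  const uword ne = edge.n_rows;
  const uword npat = tip_states.n_cols;
  const uword ns = pi.n_elem;
  const int n_node = edge.max();

  cube partial(ns, npat, n_node - n_tip, fill::zeros);
  mat logscale(n_node - n_tip, npat, fill::zeros);
  std::vector<bool> seen(n_node + 1, false);
  mat msg(ns, npat);

  for (uword e = 0; e < ne; ++e) {
    const int child = edge(e, 1), parent = edge(e, 0);
    const int pslot = parent - n_tip - 1;
    const mat& Pe = ((int)(e + 1) == fg_edge) ? P_fg : P.slice(e);
    rowvec child_scale;
    if (child <= n_tip) {
      for (uword s = 0; s < npat; ++s) {
        const int st = tip_states(child - 1, s);
        if (st > 0) msg.col(s) = Pe.col(st - 1);
        else msg.col(s).ones();
      }
    } else {
      msg = Pe * partial.slice(child - n_tip - 1);
      child_scale = logscale.row(child - n_tip - 1);
    }
    if (!seen[parent]) {
      partial.slice(pslot) = msg;
      logscale.row(pslot) = child_scale.n_elem ? child_scale
                                               : rowvec(npat, fill::zeros);
      seen[parent] = true;
    } else {
      partial.slice(pslot) %= msg;
      if (child_scale.n_elem) logscale.row(pslot) += child_scale;
    }
    rowvec mx = max(partial.slice(pslot), 0);
    for (uword s = 0; s < npat; ++s) {
      if (mx(s) > 0 && (mx(s) < 1e-40 || mx(s) > 1e40)) {
        partial.slice(pslot).col(s) /= mx(s);
        logscale(pslot, s) += std::log(mx(s));
      }
    }
  }
  const int root = edge(ne - 1, 0);
  vec out(npat);
  for (uword s = 0; s < npat; ++s) {
    const double L = dot(pi, partial.slice(root - n_tip - 1).col(s));
    out(s) = std::log(L) + logscale(root - n_tip - 1, s);
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = out,
                            Rcpp::Named("partial") = partial,
                            Rcpp::Named("logscale") = logscale);
}

// Recompute only the foreground-edge-to-root path on top of a stored pass,
// overriding the foreground edge's transition matrix with P_fg.
// [[Rcpp::export]]
arma::vec prune_fg_update_cpp(const arma::imat& edge, int n_tip,
                              const arma::cube& P, int fg_edge,
                              const arma::mat& P_fg,
                              const arma::imat& tip_states,
                              const arma::vec& pi,
                              const arma::cube& partial0,
                              const arma::mat& logscale0) {
  const uword ne = edge.n_rows;
  const uword npat = tip_states.n_cols;
  const uword ns = pi.n_elem;
  const int n_node = edge.max();

  // nodes whose partial changes: fg parent and its ancestors
  std::vector<bool> dirty(n_node + 1, false);
  {
    int cur = edge(fg_edge - 1, 0);
    dirty[cur] = true;
    bool changed = true;
    while (changed) {
      changed = false;
      for (uword e = 0; e < ne; ++e) {
        if (dirty[edge(e, 1)] && !dirty[edge(e, 0)]) {
          dirty[edge(e, 0)] = true;
          changed = true;
        }
      }
    }
  }

  std::vector<mat> partial(n_node + 1);
  std::vector<rowvec> logscale(n_node + 1);
  std::vector<bool> seen(n_node + 1, false);
  mat msg(ns, npat);

  for (uword e = 0; e < ne; ++e) {
    const int child = edge(e, 1), parent = edge(e, 0);
    if (!dirty[parent]) continue;
    const mat& Pe = ((int)(e + 1) == fg_edge) ? P_fg : P.slice(e);
    rowvec child_scale;
    if (child <= n_tip) {
      for (uword s = 0; s < npat; ++s) {
        const int st = tip_states(child - 1, s);
        if (st > 0) msg.col(s) = Pe.col(st - 1);
        else msg.col(s).ones();
      }
    } else if (dirty[child]) {
      msg = Pe * partial[child];
      child_scale = logscale[child];
      partial[child].reset();
    } else {
      msg = Pe * partial0.slice(child - n_tip - 1);
      child_scale = logscale0.row(child - n_tip - 1);
    }
    if (!seen[parent]) {
      partial[parent] = msg;
      logscale[parent] = child_scale.n_elem ? child_scale
                                            : rowvec(npat, fill::zeros);
      seen[parent] = true;
    } else {
      partial[parent] %= msg;
      if (child_scale.n_elem) logscale[parent] += child_scale;
    }
    rowvec mx = max(partial[parent], 0);
    for (uword s = 0; s < npat; ++s) {
      if (mx(s) > 0 && (mx(s) < 1e-40 || mx(s) > 1e40)) {
        partial[parent].col(s) /= mx(s);
        logscale[parent](s) += std::log(mx(s));
      }
    }
  }
  const int root = edge(ne - 1, 0);
  vec out(npat);
  for (uword s = 0; s < npat; ++s) {
    const double L = dot(pi, partial[root].col(s));
    out(s) = std::log(L) + logscale[root](s);
  }
  return out;
}
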