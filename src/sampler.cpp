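#include <Rcpp.h>
using namespace Rcpp;

// Incremental state kept per locus: d = b - bhat, Hd = H d, and the
// approximate log-likelihood ll = g'd + d'Hd/2. All updates below keep the
// three mutually consistent; refresh_state() rebuilds them from scratch.

// [[Rcpp::export]]
double quad_ll(NumericVector d, NumericVector g, NumericMatrix H) {
  int B = d.size();
  double lin = 0.0, quad = 0.0;
  for (int i = 0; i < B; i++) {
    lin += g[i] * d[i];
    double hi = 0.0;
    for (int j = 0; j < B; j++) hi += H(i, j) * d[j];
    quad += d[i] * hi;
  }
  return lin + 0.5 * quad;
}

// [[Rcpp::export]]
void refresh_state(NumericMatrix b, NumericMatrix bhat, NumericMatrix g,
                   List Hlist, NumericMatrix d, NumericMatrix Hd,
                   NumericVector ll) {
  int B = b.nrow(), L = b.ncol();
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    for (int i = 0; i < B; i++) d(i, l) = b(i, l) - bhat(i, l);
    double tot = 0.0;
    for (int i = 0; i < B; i++) {
      double hi = 0.0;
      for (int j = 0; j < B; j++) hi += H(i, j) * d(j, l);
      Hd(i, l) = hi;
      tot += g(i, l) * d(i, l) + 0.5 * d(i, l) * hi;
    }
    ll[l] = tot;
  }
}

// Log-likelihood change from perturbing the rows `rows` (0-based edge
// indices) of d by `delta` (length(rows) x L), per locus.
// [[Rcpp::export]]
NumericVector ll_delta_edges(IntegerVector rows, NumericMatrix delta,
                             NumericMatrix g, NumericMatrix Hd, List Hlist) {
  int R = rows.size(), L = delta.ncol();
  NumericVector out(L);
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    double s = 0.0;
    for (int a = 0; a < R; a++) {
      int e = rows[a];
      double de = delta(a, l);
      s += (g(e, l) + Hd(e, l)) * de;
      for (int bI = 0; bI < R; bI++)
        s += 0.5 * H(e, rows[bI]) * de * delta(bI, l);
    }
    out[l] = s;
  }
  return out;
}

// [[Rcpp::export]]
void apply_delta_edges(IntegerVector rows, NumericMatrix delta,
                       NumericMatrix d, NumericMatrix Hd, List Hlist,
                       NumericVector ll, NumericVector dll) {
  int R = rows.size(), L = delta.ncol(), B = d.nrow();
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    for (int a = 0; a < R; a++) {
      int e = rows[a];
      double de = delta(a, l);
      d(e, l) += de;
      for (int i = 0; i < B; i++) Hd(i, l) += H(i, e) * de;
    }
    ll[l] += dll[l];
  }
}

// One Metropolis sweep over all branch log-rates, ILN clock.
// X: B x L log branch rates; mlog[l] = log(mu_l) - s2_l/2.
// [[Rcpp::export]]
int iln_sweep(NumericMatrix X, NumericMatrix d, NumericMatrix Hd,
              NumericVector ll, NumericMatrix g, List Hlist,
              NumericVector dt, NumericVector mlog, NumericVector s2,
              double step) {
  int B = X.nrow(), L = X.ncol(), acc = 0;
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    for (int j = 0; j < B; j++) {
      double x = X(j, l);
      double xn = x + step * norm_rand();
      double de = (exp(xn) - exp(x)) * dt[j];
      double dll = (g(j, l) + Hd(j, l)) * de + 0.5 * H(j, j) * de * de;
      double r = x - mlog[l], rn = xn - mlog[l];
      double dlp = (r * r - rn * rn) / (2.0 * s2[l]);
      if (log(unif_rand()) < dll + dlp) {
        X(j, l) = xn;
        d(j, l) += de;
        for (int i = 0; i < B; i++) Hd(i, l) += H(i, j) * de;
        ll[l] += dll;
        acc++;
      }
    }
  }
  return acc;
}

// One Metropolis sweep over all node log-rates, GBM clock.
// X: n_all x L log node rates. node_parent_edge: per node the 0-based edge
// index whose child it is (-1 for the root); node_child_edges: per node the
// 0-based indices of its child edges. edge_parent/edge_child: 0-based node
// ids per canonical edge. Tip nodes carry rates too (they bound tip
// branches) but have no child edges.
// [[Rcpp::export]]
int gbm_sweep(NumericMatrix X, NumericMatrix d, NumericMatrix Hd,
              NumericVector ll, NumericMatrix g, List Hlist,
              NumericVector dt, IntegerVector edge_parent,
              IntegerVector edge_child, IntegerVector node_parent_edge,
              List node_child_edges, NumericVector mlog, NumericVector s2,
              double step, int root) {
  int L = X.ncol(), n_all = X.nrow(), B = dt.size(), acc = 0;
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    for (int n = 0; n < n_all; n++) {
      double x = X(n, l);
      double xn = x + step * norm_rand();
      // prior change
      double dlp = 0.0;
      if (n == root) {
        double r = x - mlog[l], rn = xn - mlog[l];
        dlp += (r * r - rn * rn) / (2.0 * s2[l]);
      } else {
        int pe = node_parent_edge[n];
        double v = s2[l] * dt[pe];
        double m = X(edge_parent[pe], l) - v / 2.0;
        double r = x - m, rn = xn - m;
        dlp += (r * r - rn * rn) / (2.0 * v);
      }
      IntegerVector ce = node_child_edges[n];
      for (int k = 0; k < ce.size(); k++) {
        double v = s2[l] * dt[ce[k]];
        double xc = X(edge_child[ce[k]], l);
        double r = xc - (x - v / 2.0), rn = xc - (xn - v / 2.0);
        dlp += (r * r - rn * rn) / (2.0 * v);
      }
      // likelihood change on adjacent edges (branch rate = endpoint mean)
      double half = 0.5 * (exp(xn) - exp(x));
      int ne = ce.size() + (n == root ? 0 : 1);
      std::vector<int> ed(ne);
      std::vector<double> de(ne);
      for (int k = 0; k < ce.size(); k++) {
        ed[k] = ce[k];
        de[k] = half * dt[ce[k]];
      }
      if (n != root) {
        ed[ne - 1] = node_parent_edge[n];
        de[ne - 1] = half * dt[ed[ne - 1]];
      }
      double dll = 0.0;
      for (int a = 0; a < ne; a++) {
        dll += (g(ed[a], l) + Hd(ed[a], l)) * de[a];
        for (int bI = 0; bI < ne; bI++)
          dll += 0.5 * H(ed[a], ed[bI]) * de[a] * de[bI];
      }
      if (log(unif_rand()) < dll + dlp) {
        X(n, l) = xn;
        for (int a = 0; a < ne; a++) {
          d(ed[a], l) += de[a];
          for (int i = 0; i < B; i++) Hd(i, l) += H(i, ed[a]) * de[a];
        }
        ll[l] += dll;
        acc++;
      }
    }
  }
  return acc;
}

static inline double iln_rp(NumericMatrix X, int l, double mlog, double s2) {
  int B = X.nrow();
  double s = -0.5 * B * log(2.0 * M_PI * s2), q = 0.0;
  for (int j = 0; j < B; j++) {
    double r = X(j, l) - mlog;
    q += r * r;
  }
  return s - q / (2.0 * s2);
}

static inline double iln_rp_vec(NumericVector x, double mlog, double s2) {
  int B = x.size();
  double s = -0.5 * B * log(2.0 * M_PI * s2), q = 0.0;
  for (int j = 0; j < B; j++) {
    double r = x[j] - mlog;
    q += r * r;
  }
  return s - q / (2.0 * s2);
}

static inline double quad_col(NumericVector dcol, NumericMatrix g, int l,
                              NumericMatrix H) {
  int B = dcol.size();
  double lin = 0.0, quad = 0.0;
  for (int i = 0; i < B; i++) {
    lin += g(i, l) * dcol[i];
    double hi = 0.0;
    for (int j = 0; j < B; j++) hi += H(i, j) * dcol[j];
    quad += dcol[i] * hi;
  }
  return lin + 0.5 * quad;
}

static inline void commit_col(NumericMatrix X, NumericMatrix d,
                              NumericMatrix Hd, NumericVector ll,
                              NumericVector rp, int l, NumericVector x_new,
                              NumericVector d_new, double ll_new,
                              double rp_new, NumericMatrix H) {
  int B = d.nrow(), n = x_new.size();
  for (int j = 0; j < n; j++) X(j, l) = x_new[j];
  for (int j = 0; j < B; j++) d(j, l) = d_new[j];
  for (int i = 0; i < B; i++) {
    double hi = 0.0;
    for (int j = 0; j < B; j++) hi += H(i, j) * d_new[j];
    Hd(i, l) = hi;
  }
  ll[l] = ll_new;
  rp[l] = rp_new;
}

// Per-locus hyperparameter and whole-locus moves, ILN clock: mu and sigma2
// random-walk moves, whole-locus rate scale, joint (mu, rates) scale, and
// the joint (sigma2, rates) rescale. One call per sweep.
// [[Rcpp::export]]
IntegerVector iln_hyper_sweep(NumericMatrix X, NumericMatrix d,
                              NumericMatrix Hd, NumericVector ll,
                              NumericMatrix g, List Hlist,
                              NumericMatrix bhat, NumericVector dt,
                              NumericVector mu, NumericVector s2,
                              NumericVector mlog, NumericVector rp,
                              NumericVector hyperpar, NumericVector steps) {
  int B = X.nrow(), L = X.ncol();
  double a_r = hyperpar[0], b_r = hyperpar[1];
  double a_s = hyperpar[2], b_s = hyperpar[3];
  IntegerVector acc(5);
  NumericVector x_new(B), d_new(B);
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    // mu random walk (rates fixed)
    {
      double u = mu[l] * exp(steps[0] * (unif_rand() - 0.5));
      double ml = log(u) - s2[l] / 2.0;
      double rp_new = iln_rp(X, l, ml, s2[l]);
      double a = R::dgamma(u, a_r, 1.0 / b_r, 1) -
                 R::dgamma(mu[l], a_r, 1.0 / b_r, 1) +
                 rp_new - rp[l] + log(u / mu[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        mu[l] = u; mlog[l] = ml; rp[l] = rp_new; acc[0]++;
      }
    }
    // sigma2 random walk (rates fixed)
    {
      double v = s2[l] * exp(steps[1] * (unif_rand() - 0.5));
      double ml = log(mu[l]) - v / 2.0;
      double rp_new = iln_rp(X, l, ml, v);
      double a = R::dgamma(v, a_s, 1.0 / b_s, 1) -
                 R::dgamma(s2[l], a_s, 1.0 / b_s, 1) +
                 rp_new - rp[l] + log(v / s2[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        s2[l] = v; mlog[l] = ml; rp[l] = rp_new; acc[1]++;
      }
    }
    // whole-locus rate scale
    {
      double eps = steps[2] * norm_rand();
      double sc = exp(eps);
      for (int j = 0; j < B; j++) {
        x_new[j] = X(j, l) + eps;
        d_new[j] = sc * (d(j, l) + bhat(j, l)) - bhat(j, l);
      }
      double ll_new = quad_col(d_new, g, l, H);
      double rp_new = iln_rp_vec(x_new, mlog[l], s2[l]);
      double a = (ll_new - ll[l]) + (rp_new - rp[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        commit_col(X, d, Hd, ll, rp, l, x_new, d_new, ll_new, rp_new, H);
        acc[2]++;
      }
    }
    // joint (mu, rates) scale: rate-prior term invariant
    {
      double eps = steps[3] * norm_rand();
      double u = mu[l] * exp(eps);
      double sc = exp(eps);
      for (int j = 0; j < B; j++) {
        x_new[j] = X(j, l) + eps;
        d_new[j] = sc * (d(j, l) + bhat(j, l)) - bhat(j, l);
      }
      double ll_new = quad_col(d_new, g, l, H);
      double a = R::dgamma(u, a_r, 1.0 / b_r, 1) -
                 R::dgamma(mu[l], a_r, 1.0 / b_r, 1) +
                 (ll_new - ll[l]) + log(u / mu[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        double ml = log(u) - s2[l] / 2.0;
        commit_col(X, d, Hd, ll, rp, l, x_new, d_new, ll_new, rp[l], H);
        mu[l] = u; mlog[l] = ml;
        acc[3]++;
      }
    }
    // joint (sigma2, rates) rescale
    {
      double eps = steps[4] * norm_rand();
      double v = s2[l] * exp(eps);
      double sig_ratio = sqrt(v / s2[l]);
      double ml = log(mu[l]) - v / 2.0;
      for (int j = 0; j < B; j++) {
        x_new[j] = ml + (X(j, l) - mlog[l]) * sig_ratio;
        d_new[j] = exp(x_new[j]) * dt[j] - bhat(j, l);
      }
      double ll_new = quad_col(d_new, g, l, H);
      double rp_new = iln_rp_vec(x_new, ml, v);
      double a = R::dgamma(v, a_s, 1.0 / b_s, 1) -
                 R::dgamma(s2[l], a_s, 1.0 / b_s, 1) +
                 (ll_new - ll[l]) + (rp_new - rp[l]) +
                 log(v / s2[l]) + B * log(sig_ratio);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        commit_col(X, d, Hd, ll, rp, l, x_new, d_new, ll_new, rp_new, H);
        s2[l] = v; mlog[l] = ml;
        acc[4]++;
      }
    }
  }
  return acc;
}

// Per-locus hyperparameter and whole-locus moves, GBM clock.
// [[Rcpp::export]]
IntegerVector gbm_hyper_sweep(NumericMatrix X, NumericMatrix d,
                              NumericMatrix Hd, NumericVector ll,
                              NumericMatrix g, List Hlist,
                              NumericMatrix bhat, NumericVector dt,
                              IntegerVector edge_parent,
                              IntegerVector edge_child,
                              NumericVector mu, NumericVector s2,
                              NumericVector mlog, NumericVector rp,
                              NumericVector hyperpar, NumericVector steps,
                              int root) {
  int B = d.nrow(), L = X.ncol(), n_all = X.nrow();
  double a_r = hyperpar[0], b_r = hyperpar[1];
  double a_s = hyperpar[2], b_s = hyperpar[3];
  IntegerVector acc(5);
  NumericVector x_new(n_all), d_new(B);
  for (int l = 0; l < L; l++) {
    NumericMatrix H = Hlist[l];
    // mu random walk: only the root-rate term involves mu
    {
      double u = mu[l] * exp(steps[0] * (unif_rand() - 0.5));
      double ml = log(u) - s2[l] / 2.0;
      double dr = R::dnorm(X(root, l), ml, sqrt(s2[l]), 1) -
                  R::dnorm(X(root, l), mlog[l], sqrt(s2[l]), 1);
      double a = R::dgamma(u, a_r, 1.0 / b_r, 1) -
                 R::dgamma(mu[l], a_r, 1.0 / b_r, 1) + dr +
                 log(u / mu[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        mu[l] = u; mlog[l] = ml; rp[l] += dr; acc[0]++;
      }
    }
    // sigma2 random walk: all autocorrelation terms change
    {
      double v = s2[l] * exp(steps[1] * (unif_rand() - 0.5));
      double ml = log(mu[l]) - v / 2.0;
      double rp_new = R::dnorm(X(root, l), ml, sqrt(v), 1);
      for (int e = 0; e < B; e++) {
        double ve = v * dt[e];
        rp_new += R::dnorm(X(edge_child[e], l),
                           X(edge_parent[e], l) - ve / 2.0, sqrt(ve), 1);
      }
      double a = R::dgamma(v, a_s, 1.0 / b_s, 1) -
                 R::dgamma(s2[l], a_s, 1.0 / b_s, 1) +
                 rp_new - rp[l] + log(v / s2[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        s2[l] = v; mlog[l] = ml; rp[l] = rp_new; acc[1]++;
      }
    }
    // whole-locus rate scale: differences invariant, root term changes
    {
      double eps = steps[2] * norm_rand();
      double sc = exp(eps);
      for (int j = 0; j < n_all; j++) x_new[j] = X(j, l) + eps;
      for (int e = 0; e < B; e++)
        d_new[e] = sc * (d(e, l) + bhat(e, l)) - bhat(e, l);
      double ll_new = quad_col(d_new, g, l, H);
      double dr = R::dnorm(x_new[root], mlog[l], sqrt(s2[l]), 1) -
                  R::dnorm(X(root, l), mlog[l], sqrt(s2[l]), 1);
      double a = (ll_new - ll[l]) + dr;
      if (R_FINITE(a) && log(unif_rand()) < a) {
        commit_col(X, d, Hd, ll, rp, l, x_new, d_new, ll_new, rp[l] + dr, H);
        acc[2]++;
      }
    }
    // joint (mu, rates) scale: rate prior fully invariant
    {
      double eps = steps[3] * norm_rand();
      double u = mu[l] * exp(eps);
      double sc = exp(eps);
      for (int j = 0; j < n_all; j++) x_new[j] = X(j, l) + eps;
      for (int e = 0; e < B; e++)
        d_new[e] = sc * (d(e, l) + bhat(e, l)) - bhat(e, l);
      double ll_new = quad_col(d_new, g, l, H);
      double a = R::dgamma(u, a_r, 1.0 / b_r, 1) -
                 R::dgamma(mu[l], a_r, 1.0 / b_r, 1) +
                 (ll_new - ll[l]) + log(u / mu[l]);
      if (R_FINITE(a) && log(unif_rand()) < a) {
        commit_col(X, d, Hd, ll, rp, l, x_new, d_new, ll_new, rp[l], H);
        mu[l] = u; mlog[l] = log(u) - s2[l] / 2.0;
        acc[3]++;
      }
    }
  }
  return acc;
}
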