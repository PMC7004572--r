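// Compiled cores for the two regression engines:
//  - exhaustive best-subset OLS scored by BIC (single-task)
//  - multitask sparse regression, W = S + B with l1/l1 and l1/linf
//    penalties, solved by alternating coordinate-descent / proximal steps
//    over an (lambda_s, lambda_b) grid scored by extended BIC.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double subset_rss(const arma::mat& AtA, const arma::vec& Aty,
                         double yty, const arma::uvec& idx, arma::vec& beta) {
  if (idx.n_elem == 0) { beta.reset(); return yty; }
  arma::mat G = AtA.submat(idx, idx);
  arma::vec b = Aty.elem(idx);
  bool ok = arma::solve(beta, G, b, arma::solve_opts::no_approx);
  if (!ok) beta = arma::pinv(G) * b;
  double rss = yty - arma::dot(beta, b) * 2.0 + arma::as_scalar(beta.t() * G * beta);
  return std::max(rss, 0.0);
}

// Exhaustive best-subset regression. A: n x p centered predictors,
// y: centered response. BIC = n*log(rss/n) + q*log(n); ties at 1e-9 go to
// the smaller subset, then to the lexicographically first index set.
// [[Rcpp::export]]
List best_subset_core(const arma::mat& A, const arma::vec& y) {
  const int n = A.n_rows, p = A.n_cols;
  if (p > 20) stop("too many predictors for exhaustive enumeration");
  arma::mat AtA = A.t() * A;
  arma::vec Aty = A.t() * y;
  double yty = arma::dot(y, y);
  const double tiny = 1e-12, tol = 1e-9;
  const unsigned long nsub = 1UL << p;

  double best_bic = R_PosInf;
  arma::uvec best_idx;
  arma::vec best_beta;
  double best_rss = yty;

  arma::vec beta;
  for (unsigned long mask = 0; mask < nsub; ++mask) {
    int q = __builtin_popcountl(mask);
    arma::uvec idx(q);
    for (int j = 0, t = 0; j < p; ++j) if (mask & (1UL << j)) idx[t++] = j;
    double rss = subset_rss(AtA, Aty, yty, idx, beta);
    double bic = n * std::log(std::max(rss, tiny) / n) + q * std::log((double)n);
    bool take = false;
    if (bic < best_bic - tol) take = true;
    else if (std::fabs(bic - best_bic) <= tol) {
      if (q < (int)best_idx.n_elem) take = true;
      else if (q == (int)best_idx.n_elem) {
        for (int t = 0; t < q; ++t) {
          if (idx[t] < best_idx[t]) { take = true; break; }
          if (idx[t] > best_idx[t]) break;
        }
      }
    }
    if (take) { best_bic = bic; best_idx = idx; best_beta = beta; best_rss = rss; }
  }

  // per-regulator explained variance: 1 - rss_full / rss_without_k
  int q = best_idx.n_elem;
  arma::vec varexp(q, arma::fill::zeros);
  for (int t = 0; t < q; ++t) {
    arma::uvec drop(q - 1);
    for (int s = 0, u = 0; s < q; ++s) if (s != t) drop[u++] = best_idx[s];
    arma::vec bd;
    double rss_drop = subset_rss(AtA, Aty, yty, drop, bd);
    double ve = (rss_drop <= tiny) ? 0.0 : 1.0 - best_rss / rss_drop;
    varexp[t] = std::min(1.0, std::max(0.0, ve));
  }

  double tss = yty;
  double r2 = (tss <= tiny) ? 0.0 : std::min(1.0, std::max(0.0, 1.0 - best_rss / tss));
  return List::create(_["idx"] = IntegerVector(best_idx.begin(), best_idx.end()),
                      _["beta"] = best_beta.n_elem ? NumericVector(best_beta.begin(), best_beta.end()) : NumericVector(0),
                      _["rss"] = best_rss, _["bic"] = best_bic,
                      _["var_exp"] = NumericVector(varexp.begin(), varexp.end()),
                      _["r2"] = r2);
}

// Euclidean projection of v onto the l1 ball of radius z (Duchi et al.).
static arma::vec proj_l1ball(const arma::vec& v, double z) {
  arma::vec u = arma::abs(v);
  if (arma::accu(u) <= z) return v;
  arma::vec su = arma::sort(u, "descend");
  arma::vec cs = arma::cumsum(su);
  int rho = 0;
  for (unsigned int j = 0; j < su.n_elem; ++j) {
    if (su[j] - (cs[j] - z) / (j + 1.0) > 0) rho = j;
  }
  double theta = (cs[rho] - z) / (rho + 1.0);
  arma::vec w = u - theta;
  w.elem(arma::find(w < 0)).zeros();
  return arma::sign(v) % w;
}

struct TaskData {
  arma::mat AtA;
  arma::vec Aty;
  double yty;
  int n;
  arma::vec diag;
};

static double amusr_objective(const std::vector<TaskData>& td,
                              const arma::mat& S, const arma::mat& B,
                              double ls, double lb) {
  double obj = 0.0;
  int d = td.size();
  for (int t = 0; t < d; ++t) {
    arma::vec w = S.col(t) + B.col(t);
    obj += td[t].yty - 2.0 * arma::dot(w, td[t].Aty) +
           arma::as_scalar(w.t() * td[t].AtA * w);
  }
  obj += ls * arma::accu(arma::abs(S));
  obj += lb * arma::accu(arma::max(arma::abs(B), 1));
  return obj;
}

// One (lambda_s, lambda_b) fit by alternating exact coordinate descent on S
// (soft-thresholding) and a proximal gradient step on B (l1/linf prox via
// l1-ball projection). Returns S, B and the objective trace.
static void amusr_fit_one(const std::vector<TaskData>& td, int p,
                          double ls, double lb, int max_iter, double tol,
                          arma::mat& S, arma::mat& B,
                          std::vector<double>& trace, double L,
                          bool warm = false) {
  int d = td.size();
  if (!warm || (int)S.n_rows != p || (int)S.n_cols != d) {
    S.zeros(p, d); B.zeros(p, d);
  }
  double step = 1.0 / L;
  trace.clear();
  double prev = amusr_objective(td, S, B, ls, lb);
  trace.push_back(prev);
  for (int it = 0; it < max_iter; ++it) {
    // B block first, so shared structure is absorbed by the conserved
    // component before the task-specific sweep. Iterated proximal gradient
    // steps with step 1/L (each a majorize-minimize step, hence monotone)
    // approximately minimize the block; exact block minimization of this
    // jointly convex objective with block-separable penalties converges to
    // a global minimizer.
    for (int inner = 0; inner < 50; ++inner) {
      arma::mat G(p, d);
      for (int t = 0; t < d; ++t) {
        arma::vec w = S.col(t) + B.col(t);
        G.col(t) = 2.0 * (td[t].AtA * w - td[t].Aty);
      }
      arma::mat V = B - step * G;
      arma::mat Bnew(p, d);
      for (int j = 0; j < p; ++j) {
        arma::rowvec vr = V.row(j);
        arma::vec pr = proj_l1ball(vr.t(), lb * step);
        Bnew.row(j) = vr - pr.t();   // Moreau: prox of c*||.||_inf
      }
      double delta = arma::abs(Bnew - B).max();
      B = Bnew;
      if (delta < 1e-6) break;
    }
    // S block: coordinate-descent sweeps per task (each update is an exact
    // 1-d minimization, hence monotone) until the sweep stops moving
    for (int inner = 0; inner < 50; ++inner) {
      double delta = 0.0;
      for (int t = 0; t < d; ++t) {
        const TaskData& T = td[t];
        for (int j = 0; j < p; ++j) {
          double ajj = T.AtA(j, j);
          if (ajj <= 1e-12) { S(j, t) = 0.0; continue; }
          arma::vec w = S.col(t) + B.col(t);
          double cj = T.Aty[j] - arma::dot(T.AtA.row(j).t(), w) + ajj * w[j] - ajj * B(j, t);
          double sj = std::fabs(cj) - ls / 2.0;
          double snew = sj > 0 ? (cj > 0 ? sj : -sj) / ajj : 0.0;
          delta = std::max(delta, std::fabs(snew - S(j, t)));
          S(j, t) = snew;
        }
      }
      if (delta < 1e-6) break;
    }
    double obj = amusr_objective(td, S, B, ls, lb);
    trace.push_back(obj);
    if (std::fabs(prev - obj) <= tol * std::max(1.0, std::fabs(prev))) { prev = obj; break; }
    prev = obj;
  }
  // hard-threshold numerically zero coefficients
  S.elem(arma::find(arma::abs(S) < 1e-9)).zeros();
  B.elem(arma::find(arma::abs(B) < 1e-9)).zeros();
}

static double lipschitz_bound(const std::vector<TaskData>& td) {
  double L = 0.0;
  for (size_t t = 0; t < td.size(); ++t) {
    double e = arma::max(arma::eig_sym(td[t].AtA));
    if (e > L) L = e;
  }
  return std::max(2.0 * L, 1e-8);
}

static std::vector<TaskData> build_tasks(const List& Alist, const List& ylist) {
  int d = Alist.size();
  std::vector<TaskData> td(d);
  for (int t = 0; t < d; ++t) {
    arma::mat A = as<arma::mat>(Alist[t]);
    arma::vec y = as<arma::vec>(ylist[t]);
    td[t].AtA = A.t() * A;
    td[t].Aty = A.t() * y;
    td[t].yty = arma::dot(y, y);
    td[t].n = A.n_rows;
    td[t].diag = td[t].AtA.diag();
  }
  return td;
}

// [[Rcpp::export]]
List amusr_core_single(List Alist, List ylist, double lambda_s,
                       double lambda_b, int max_iter, double tol) {
  std::vector<TaskData> td = build_tasks(Alist, ylist);
  int p = td[0].AtA.n_rows;
  arma::mat S, B;
  std::vector<double> trace;
  amusr_fit_one(td, p, lambda_s, lambda_b, max_iter, tol, S, B, trace,
                lipschitz_bound(td));
  return List::create(_["S"] = S, _["B"] = B,
                      _["objective"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List amusr_core_grid(List Alist, List ylist, NumericVector lambda_s,
                     NumericVector lambda_b, double gamma, int max_iter,
                     double tol) {
  std::vector<TaskData> td = build_tasks(Alist, ylist);
  int d = td.size();
  int p = td[0].AtA.n_rows;
  int ntot = 0;
  for (int t = 0; t < d; ++t) ntot += td[t].n;
  double best_ebic = R_PosInf;
  arma::mat bestS(p, d, arma::fill::zeros), bestB(p, d, arma::fill::zeros);
  double best_ls = lambda_s[0], best_lb = lambda_b[0];
  std::vector<double> best_trace(1, 0.0);
  arma::mat S, B;
  std::vector<double> trace;
  double L = lipschitz_bound(td);
  for (int g = 0; g < lambda_s.size(); ++g) {
    // warm start from the neighboring grid point: the objective is jointly
    // convex, so the minimizer is unchanged and convergence is faster
    amusr_fit_one(td, p, lambda_s[g], lambda_b[g], max_iter, tol, S, B, trace,
                  L, g > 0);
    arma::mat W = S + B;
    int q = arma::accu(arma::abs(W) > 0);
    double rss = 0.0;
    for (int t = 0; t < d; ++t) {
      arma::vec w = W.col(t);
      rss += td[t].yty - 2.0 * arma::dot(w, td[t].Aty) +
             arma::as_scalar(w.t() * td[t].AtA * w);
    }
    rss = std::max(rss, 0.0);
    double ebic = (rss <= 0.0) ? R_NegInf
      : ntot * std::log(rss / ntot) + q * std::log((double)ntot) +
        2.0 * gamma * q * std::log((double)p);
    if (ebic < best_ebic) {
      best_ebic = ebic; bestS = S; bestB = B;
      best_ls = lambda_s[g]; best_lb = lambda_b[g]; best_trace = trace;
    }
  }
  return List::create(_["S"] = bestS, _["B"] = bestB, _["ebic"] = best_ebic,
                      _["lambda_s"] = best_ls, _["lambda_b"] = best_lb,
                      _["objective"] = NumericVector(best_trace.begin(), best_trace.end()));
}
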