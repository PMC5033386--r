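// Bayesian divergence dating core: Felsenstein pruning likelihood under
// HKY with 4-category discrete Gamma rates, a Yule prior on node ages,
// and a Metropolis-Hastings sampler over node ages, HKY kappa, Gamma
// shape, Yule birth rate and per-branch clock rates (strict, random
// local, or iid-exponential relaxed clock). Topology is fixed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// TN93-style closed-form HKY transition probabilities.
// Order of states: A, C, G, T. d = expected substitutions/site.
static void hky_pmat(double d, double kappa, const double* pi, double* P) {
  double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
  double piR = piA + piG, piY = piC + piT;
  // normalise so mean rate is 1: rate = 2*kappa*b*(piA*piG + piC*piT)
  //                                   + 2*b*piR*piY
  double b = 1.0 / (2.0 * kappa * (piA * piG + piC * piT) +
                    2.0 * piR * piY);
  double a = kappa * b;
  double e2 = std::exp(-b * d);
  double eR = std::exp(-(piR * a + piY * b) * d);
  double eY = std::exp(-(piY * a + piR * b) * d);
  // helper lambdas over indices: purines {0,2}, pyrimidines {1,3}
  for (int i = 0; i < 4; i++) {
    for (int j = 0; j < 4; j++) {
      double pij;
      bool ri = (i == 0 || i == 2), rj = (j == 0 || j == 2);
      double pj = pi[j];
      if (ri && rj) {
        if (i == j)
          pij = pj + pj * (piY / piR) * e2 + ((piR - pj) / piR) * eR;
        else
          pij = pj + pj * (piY / piR) * e2 - (pj / piR) * eR;
      } else if (!ri && !rj) {
        if (i == j)
          pij = pj + pj * (piR / piY) * e2 + ((piY - pj) / piY) * eY;
        else
          pij = pj + pj * (piR / piY) * e2 - (pj / piY) * eY;
      } else {
        pij = pj * (1.0 - e2);
      }
      P[4 * i + j] = pij;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix hky_pmat_cpp(double d, double kappa, NumericVector pi) {
  NumericMatrix P(4, 4);
  double Pp[16];
  hky_pmat(d, kappa, pi.begin(), Pp);
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++) P(i, j) = Pp[4 * i + j];
  return P;
}

// 4-category discrete Gamma (median method), normalised to mean 1
static void gamma_rates4(double shape, double* r) {
  if (shape <= 0 || shape > 1e6) {
    for (int k = 0; k < 4; k++) r[k] = 1.0;
    return;
  }
  double m = 0;
  for (int k = 0; k < 4; k++) {
    r[k] = R::qgamma((2.0 * k + 1.0) / 8.0, shape, 1.0 / shape, 1, 0);
    m += r[k];
  }
  m /= 4.0;
  for (int k = 0; k < 4; k++) r[k] /= m;
}

struct TreeData {
  int n_tip, n_node;            // total nodes = 2*n_tip - 1
  std::vector<int> kid1, kid2;  // children of internal nodes (-1 for tips)
  std::vector<int> parent;
  std::vector<int> postorder;   // internal nodes in postorder
  IntegerMatrix tipstate;       // n_tip x npat, 0..3 or -1 (ambiguous)
  NumericVector patw;           // pattern weights
  int npat;
};

// pruning log-likelihood; ages in My, branch rate (subs/site/My) per node
// (rate of the branch above that node)
static double loglik(const TreeData& T, const std::vector<double>& age,
                     const std::vector<double>& brate, double kappa,
                     double shape, const double* pi) {
  double gr[4];
  gamma_rates4(shape, gr);
  int npat = T.npat;
  int nn = T.n_node;
  std::vector<double> partial(nn * 4);
  NumericVector sitelik(npat);
  double ll = 0.0;
  // accumulate per category then average
  std::vector<double> catlik(npat, 0.0);
  for (int c = 0; c < 4; c++) {
    std::vector<std::vector<double>> L(nn);
    for (int k = 0; k < (int)T.postorder.size(); k++) {
      int nd = T.postorder[k];
      int c1 = T.kid1[nd], c2 = T.kid2[nd];
      // transition matrices for the two child branches
      double P1[16], P2[16];
      double d1 = (age[nd] - age[c1]) * brate[c1] * gr[c];
      double d2 = (age[nd] - age[c2]) * brate[c2] * gr[c];
      if (d1 < 0 || d2 < 0) return -INFINITY;
      hky_pmat(d1, kappa, pi, P1);
      hky_pmat(d2, kappa, pi, P2);
      L[nd].assign(4 * npat, 0.0);
      const std::vector<double>* L1 =
          (c1 >= T.n_tip) ? &L[c1] : nullptr;
      const std::vector<double>* L2 =
          (c2 >= T.n_tip) ? &L[c2] : nullptr;
      for (int s = 0; s < npat; s++) {
        double v1[4], v2[4];
        if (L1) {
          for (int i = 0; i < 4; i++) {
            double a = 0;
            for (int j = 0; j < 4; j++) a += P1[4 * i + j] * (*L1)[4 * s + j];
            v1[i] = a;
          }
        } else {
          int st = T.tipstate(c1, s);
          for (int i = 0; i < 4; i++)
            v1[i] = (st < 0) ? 1.0 : P1[4 * i + st];
        }
        if (L2) {
          for (int i = 0; i < 4; i++) {
            double a = 0;
            for (int j = 0; j < 4; j++) a += P2[4 * i + j] * (*L2)[4 * s + j];
            v2[i] = a;
          }
        } else {
          int st = T.tipstate(c2, s);
          for (int i = 0; i < 4; i++)
            v2[i] = (st < 0) ? 1.0 : P2[4 * i + st];
        }
        for (int i = 0; i < 4; i++) L[nd][4 * s + i] = v1[i] * v2[i];
      }
      // free children partials
      if (L1) std::vector<double>().swap(L[c1]);
      if (L2) std::vector<double>().swap(L[c2]);
    }
    int root = T.postorder.back();
    for (int s = 0; s < npat; s++) {
      double a = 0;
      for (int i = 0; i < 4; i++) a += pi[i] * L[root][4 * s + i];
      catlik[s] += 0.25 * a;
    }
  }
  for (int s = 0; s < npat; s++) {
    if (catlik[s] <= 0) return -INFINITY;
    ll += T.patw[s] * std::log(catlik[s]);
  }
  return ll;
}

// Yule log prior on node ages of a fixed labelled topology with n tips:
// (n-2) log(lambda) - lambda * total tree length
static double yule_logprior(const TreeData& T, const std::vector<double>& age,
                            double lambda) {
  double tl = 0.0;
  for (int nd = 0; nd < T.n_node; nd++) {
    if (T.parent[nd] >= 0) tl += age[T.parent[nd]] - age[nd];
  }
  return (T.n_tip - 2) * std::log(lambda) - lambda * tl;
}

// [[Rcpp::export]]
double pruning_loglik_cpp(IntegerVector kid1, IntegerVector kid2,
                          IntegerVector parent, IntegerVector postorder,
                          IntegerMatrix tipstate, NumericVector patw,
                          NumericVector age, NumericVector brate,
                          double kappa, double shape, NumericVector pi) {
  TreeData T;
  T.n_tip = tipstate.nrow();
  T.n_node = kid1.size();
  T.kid1 = as<std::vector<int>>(kid1);
  T.kid2 = as<std::vector<int>>(kid2);
  T.parent = as<std::vector<int>>(parent);
  T.postorder = as<std::vector<int>>(postorder);
  T.tipstate = tipstate;
  T.patw = patw;
  T.npat = tipstate.ncol();
  std::vector<double> a = as<std::vector<double>>(age);
  std::vector<double> b = as<std::vector<double>>(brate);
  return loglik(T, a, b, kappa, shape, pi.begin());
}

// clock models
enum Clock { STRICT = 0, RANDOM_LOCAL = 1, RELAXED_EXP = 2 };

// effective branch rates for the random local clock: each branch carries
// an indicator delta and multiplier phi; the branch rate is the base rate
// times the product of phi over flagged ancestors (including itself)
static void rlc_rates(const TreeData& T, double base,
                      const std::vector<int>& delta,
                      const std::vector<double>& phi,
                      std::vector<double>& out) {
  // parents are always later in postorder; compute top-down via repeated
  // passes from root using parent pointers
  int root = T.postorder.back();
  out.assign(T.n_node, base);
  // process nodes in reverse postorder so parents are done first
  std::vector<int> order;
  order.push_back(root);
  for (int k = (int)T.postorder.size() - 1; k >= 0; k--) {
    int nd = T.postorder[k];
    order.push_back(T.kid1[nd]);
    order.push_back(T.kid2[nd]);
  }
  for (int idx = 0; idx < (int)order.size(); idx++) {
    int nd = order[idx];
    double parent_rate = (T.parent[nd] >= 0) ? out[T.parent[nd]] : base;
    out[nd] = delta[nd] ? parent_rate * phi[nd] : parent_rate;
  }
}

// [[Rcpp::export]]
List mcmc_chain_cpp(IntegerVector kid1, IntegerVector kid2,
                    IntegerVector parent, IntegerVector postorder,
                    IntegerMatrix tipstate, NumericVector patw,
                    NumericVector init_age, double clock_rate,
                    int clock_model, NumericVector pi,
                    double init_kappa, double init_shape,
                    double init_lambda, bool sample_lambda,
                    double lambda_prior_rate,
                    long generations, long burnin, int thin,
                    bool likelihood_on,
                    double rlc_bernoulli_p, double rlc_phi_sdlog,
                    NumericVector age_min) {
  RNGScope scope; // draws come from R's RNG: set.seed() upstream fixes them
  TreeData T;
  T.n_tip = tipstate.nrow();
  T.n_node = kid1.size();
  T.kid1 = as<std::vector<int>>(kid1);
  T.kid2 = as<std::vector<int>>(kid2);
  T.parent = as<std::vector<int>>(parent);
  T.postorder = as<std::vector<int>>(postorder);
  T.tipstate = tipstate;
  T.patw = patw;
  T.npat = tipstate.ncol();
  int nn = T.n_node, ntip = T.n_tip;
  int nint = nn - ntip;

  std::vector<double> age = as<std::vector<double>>(init_age);
  double kappa = init_kappa, shape = init_shape, lambda = init_lambda;
  std::vector<int> delta(nn, 0);
  std::vector<double> phi(nn, 1.0);
  std::vector<double> brate(nn, clock_rate);
  std::vector<double> amin = as<std::vector<double>>(age_min);

  // relaxed-exponential: per-branch iid rates with mean clock_rate
  if (clock_model == RELAXED_EXP) {
    for (int nd = 0; nd < nn; nd++) brate[nd] = clock_rate;
  }

  auto branch_rates = [&](std::vector<double>& out) {
    if (clock_model == STRICT) {
      out.assign(nn, clock_rate);
    } else if (clock_model == RANDOM_LOCAL) {
      rlc_rates(T, clock_rate, delta, phi, out);
    } else {
      out = brate;
    }
  };

  auto log_prior_rates = [&]() {
    double lp = 0.0;
    if (clock_model == RANDOM_LOCAL) {
      for (int nd = 0; nd < nn; nd++) {
        if (T.parent[nd] < 0) continue;
        if (delta[nd]) {
          double lphi = std::log(phi[nd]);
          lp += std::log(rlc_bernoulli_p) +
                R::dnorm(lphi, 0.0, rlc_phi_sdlog, 1) - lphi;
        } else {
          lp += std::log(1.0 - rlc_bernoulli_p);
        }
      }
    } else if (clock_model == RELAXED_EXP) {
      for (int nd = 0; nd < nn; nd++) {
        if (T.parent[nd] < 0) continue;
        lp += R::dexp(brate[nd], clock_rate, 1);
      }
    }
    return lp;
  };

  // hyperpriors: kappa ~ LogNormal(1, 1.25); shape ~ LogNormal(0, 1);
  // lambda ~ Exp(lambda_prior_rate)
  auto log_prior_params = [&]() {
    double lp = R::dlnorm(kappa, 1.0, 1.25, 1) +
                R::dlnorm(shape, 0.0, 1.0, 1);
    if (sample_lambda) lp += R::dexp(lambda, 1.0 / lambda_prior_rate, 1);
    return lp;
  };

  std::vector<double> rates_now;
  branch_rates(rates_now);
  double cur_ll = likelihood_on
                      ? loglik(T, age, rates_now, kappa, shape, pi.begin())
                      : 0.0;
  double cur_lp = yule_logprior(T, age, lambda) + log_prior_params() +
                  log_prior_rates();

  int n_samples = (int)((generations - burnin) / thin) + 1;
  int ncol_out = nint + 4 + 1; // ages, kappa, shape, lambda, mean rate, ll
  NumericMatrix out(n_samples, ncol_out);
  IntegerVector state_idx(n_samples);
  int srow = 0;

  for (long g = 0; g <= generations; g++) {
    // choose a move
    double u = unif_rand();
    double prop_hastings = 0.0;
    bool valid = true;
    int which_node = -1;
    int move_type;
    if (u < 0.45) move_type = 0;           // single node age
    else if (u < 0.55) move_type = 1;      // scale all ages
    else if (u < 0.65) move_type = 2;      // kappa
    else if (u < 0.75) move_type = 3;      // shape
    else if (u < 0.75 + (sample_lambda ? 0.10 : 0.0)) move_type = 4;
    else if (clock_model != STRICT) move_type = 5;  // branch-rate move
    else move_type = 0;

    std::vector<double> age_new = age;
    double kappa_new = kappa, shape_new = shape, lambda_new = lambda;
    std::vector<int> delta_new = delta;
    std::vector<double> phi_new = phi, brate_new = brate;

    if (move_type == 0) {
      // pick internal node; slide within (max child age, parent age);
      // root: multiplicative scale of root stem above oldest child
      int k = (int)(unif_rand() * nint);
      if (k >= nint) k = nint - 1;
      which_node = ntip + k;
      double lo = std::max(age[T.kid1[which_node]],
                           age[T.kid2[which_node]]);
      lo = std::max(lo, amin[which_node]);
      if (T.parent[which_node] >= 0) {
        double hi = age[T.parent[which_node]];
        age_new[which_node] = lo + unif_rand() * (hi - lo);
      } else {
        double delta_age = age[which_node] - lo;
        double f = std::exp((unif_rand() - 0.5) * 1.0);
        age_new[which_node] = lo + delta_age * f;
        prop_hastings = std::log(f);
      }
    } else if (move_type == 1) {
      double f = std::exp((unif_rand() - 0.5) * 0.2);
      for (int nd = ntip; nd < nn; nd++) {
        age_new[nd] = age[nd] * f;
        if (age_new[nd] < amin[nd]) valid = false;
      }
      prop_hastings = nint * std::log(f);
    } else if (move_type == 2) {
      double f = std::exp((unif_rand() - 0.5) * 0.5);
      kappa_new = kappa * f;
      prop_hastings = std::log(f);
    } else if (move_type == 3) {
      double f = std::exp((unif_rand() - 0.5) * 0.8);
      shape_new = shape * f;
      prop_hastings = std::log(f);
    } else if (move_type == 4) {
      double f = std::exp((unif_rand() - 0.5) * 0.8);
      lambda_new = lambda * f;
      prop_hastings = std::log(f);
    } else {
      // branch-rate move: pick a non-root branch
      int nd;
      do { nd = (int)(unif_rand() * nn); } while (nd >= nn ||
                                                  T.parent[nd] < 0);
      if (clock_model == RANDOM_LOCAL) {
        if (unif_rand() < 0.5) {
          delta_new[nd] = 1 - delta[nd];
          if (delta_new[nd]) phi_new[nd] = std::exp(norm_rand() *
                                                    rlc_phi_sdlog);
        } else if (delta[nd]) {
          double f = std::exp((unif_rand() - 0.5) * 0.6);
          phi_new[nd] = phi[nd] * f;
          prop_hastings = std::log(f);
        }
      } else { // relaxed exponential
        double f = std::exp((unif_rand() - 0.5) * 0.8);
        brate_new[nd] = brate[nd] * f;
        prop_hastings = std::log(f);
      }
    }

    if (valid) {
      // swap in proposals
      std::swap(age, age_new);
      std::swap(kappa, kappa_new);
      std::swap(shape, shape_new);
      std::swap(lambda, lambda_new);
      std::swap(delta, delta_new);
      std::swap(phi, phi_new);
      std::swap(brate, brate_new);

      branch_rates(rates_now);
      double new_ll = likelihood_on
                          ? loglik(T, age, rates_now, kappa, shape,
                                   pi.begin())
                          : 0.0;
      double new_lp = yule_logprior(T, age, lambda) + log_prior_params() +
                      log_prior_rates();
      double logr = (new_ll + new_lp) - (cur_ll + cur_lp) + prop_hastings;
      if (std::isfinite(new_ll + new_lp) &&
          (logr >= 0 || std::log(unif_rand()) < logr)) {
        cur_ll = new_ll;
        cur_lp = new_lp;
      } else {
        // revert
        std::swap(age, age_new);
        std::swap(kappa, kappa_new);
        std::swap(shape, shape_new);
        std::swap(lambda, lambda_new);
        std::swap(delta, delta_new);
        std::swap(phi, phi_new);
        std::swap(brate, brate_new);
      }
    }

    if (g >= burnin && ((g - burnin) % thin == 0) && srow < n_samples) {
      branch_rates(rates_now);
      double mr = 0; int nb = 0;
      for (int nd = 0; nd < nn; nd++) {
        if (T.parent[nd] >= 0) { mr += rates_now[nd]; nb++; }
      }
      for (int k = 0; k < nint; k++) out(srow, k) = age[ntip + k];
      out(srow, nint) = kappa;
      out(srow, nint + 1) = shape;
      out(srow, nint + 2) = lambda;
      out(srow, nint + 3) = mr / nb;
      out(srow, nint + 4) = cur_ll;
      state_idx[srow] = (int)g;
      srow++;
    }
  }
  return List::create(_["samples"] = out, _["state"] = state_idx,
                      _["n_samples"] = srow);
}
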