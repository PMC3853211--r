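#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Log marginal likelihood of a value block under the Normal-Gamma conjugate
// model, from sufficient statistics (n, sum, sum of squares). Empty block = 0.
static inline double blm_stats(double n, double sum, double sumsq,
                               double mu0, double lambda0,
                               double alpha0, double beta0) {
  if (n <= 0) return 0.0;
  double xbar = sum / n;
  double ss = sumsq - n * xbar * xbar;
  if (ss < 0) ss = 0;  // numerical guard
  double lambda_n = lambda0 + n;
  double alpha_n = alpha0 + 0.5 * n;
  double beta_n = beta0 + 0.5 * ss +
    0.5 * lambda0 * n * (xbar - mu0) * (xbar - mu0) / lambda_n;
  return R::lgammafn(alpha_n) - R::lgammafn(alpha0) +
    alpha0 * std::log(beta0) - alpha_n * std::log(beta_n) +
    0.5 * (std::log(lambda0) - std::log(lambda_n)) -
    0.5 * n * std::log(2.0 * M_PI);
}

// [[Rcpp::export(name = ".blm_stats_cpp")]]
double blm_stats_cpp(double n, double sum, double sumsq, double mu0,
                     double lambda0, double alpha0, double beta0) {
  return blm_stats(n, sum, sumsq, mu0, lambda0, alpha0, beta0);
}

struct ClusterStats {
  int n;
  std::vector<double> sum, sumsq;
  ClusterStats(int S) : n(0), sum(S, 0.0), sumsq(S, 0.0) {}
};

// One full Gibbs scan-and-record for clustering genes (rows) over samples
// (columns), samples treated as independent blocks within a cluster.
// Returns an integer matrix of recorded assignment states (steps x genes),
// 1-based cluster labels. Uses R's RNG: seed with set.seed() beforehand.
// [[Rcpp::export(name = ".gibbs_cluster_cpp")]]
IntegerMatrix gibbs_cluster_cpp(NumericMatrix data, int burn_in, int steps,
                                double mu0, double lambda0, double alpha0,
                                double beta0, double crp_alpha) {
  const int G = data.nrow(), S = data.ncol();
  std::vector<ClusterStats> clusters;
  std::vector<int> z(G);

  // start from the all-singletons state
  for (int g = 0; g < G; ++g) {
    clusters.push_back(ClusterStats(S));
    clusters[g].n = 1;
    for (int s = 0; s < S; ++s) {
      double x = data(g, s);
      clusters[g].sum[s] = x;
      clusters[g].sumsq[s] = x * x;
    }
    z[g] = g;
  }

  IntegerMatrix states(steps, G);
  std::vector<int> order(G);
  std::vector<double> logw;

  int total_sweeps = burn_in + steps;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    // Fisher-Yates shuffle of visit order from R's RNG
    for (int g = 0; g < G; ++g) order[g] = g;
    for (int g = G - 1; g > 0; --g) {
      int j = (int)std::floor(unif_rand() * (g + 1));
      if (j > g) j = g;
      std::swap(order[g], order[j]);
    }

    for (int idx = 0; idx < G; ++idx) {
      int g = order[idx];
      int kold = z[g];
      // remove gene g from its cluster
      ClusterStats &co = clusters[kold];
      co.n -= 1;
      for (int s = 0; s < S; ++s) {
        double x = data(g, s);
        co.sum[s] -= x;
        co.sumsq[s] -= x * x;
      }
      if (co.n == 0) {  // drop empty cluster (swap with last)
        int last = (int)clusters.size() - 1;
        if (kold != last) {
          clusters[kold] = clusters[last];
          for (int gg = 0; gg < G; ++gg)
            if (z[gg] == last) z[gg] = kold;
        }
        clusters.pop_back();
      }

      int K = (int)clusters.size();
      logw.assign(K + 1, 0.0);
      double best = -INFINITY;
      for (int k = 0; k < K; ++k) {
        ClusterStats &c = clusters[k];
        double delta = 0.0;
        for (int s = 0; s < S; ++s) {
          double x = data(g, s);
          delta += blm_stats(c.n + 1, c.sum[s] + x, c.sumsq[s] + x * x,
                             mu0, lambda0, alpha0, beta0) -
                   blm_stats(c.n, c.sum[s], c.sumsq[s],
                             mu0, lambda0, alpha0, beta0);
        }
        logw[k] = std::log((double)c.n) + delta;
        if (logw[k] > best) best = logw[k];
      }
      {
        double dnew = 0.0;
        for (int s = 0; s < S; ++s) {
          double x = data(g, s);
          dnew += blm_stats(1, x, x * x, mu0, lambda0, alpha0, beta0);
        }
        logw[K] = std::log(crp_alpha) + dnew;
        if (logw[K] > best) best = logw[K];
      }
      double total = 0.0;
      for (int k = 0; k <= K; ++k) {
        logw[k] = std::exp(logw[k] - best);
        total += logw[k];
      }
      double u = unif_rand() * total;
      int knew = K;
      double acc = 0.0;
      for (int k = 0; k <= K; ++k) {
        acc += logw[k];
        if (u <= acc) { knew = k; break; }
      }
      if (knew == K) clusters.push_back(ClusterStats(S));
      ClusterStats &cn = clusters[knew];
      cn.n += 1;
      for (int s = 0; s < S; ++s) {
        double x = data(g, s);
        cn.sum[s] += x;
        cn.sumsq[s] += x * x;
      }
      z[g] = knew;
    }

    if (sweep >= burn_in) {
      int row = sweep - burn_in;
      for (int g = 0; g < G; ++g) states(row, g) = z[g] + 1;
    }
  }
  return states;
}

// Co-assignment frequency matrix over recorded states (rows = states).
// [[Rcpp::export(name = ".cocluster_cpp")]]
NumericMatrix cocluster_cpp(IntegerMatrix states) {
  const int T = states.nrow(), G = states.ncol();
  NumericMatrix co(G, G);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < G; ++i) {
      int zi = states(t, i);
      for (int j = i + 1; j < G; ++j) {
        if (states(t, j) == zi) { co(i, j) += 1.0; }
      }
    }
  }
  for (int i = 0; i < G; ++i) {
    co(i, i) = 1.0;
    for (int j = i + 1; j < G; ++j) {
      co(i, j) /= T;
      co(j, i) = co(i, j);
    }
  }
  return co;
}

// Total model score of an assignment: sum over clusters and samples of the
// block log marginal likelihood.
// [[Rcpp::export(name = ".assignment_score_cpp")]]
double assignment_score_cpp(NumericMatrix data, IntegerVector z, double mu0,
                            double lambda0, double alpha0, double beta0) {
  const int G = data.nrow(), S = data.ncol();
  int K = 0;
  for (int g = 0; g < G; ++g) if (z[g] > K) K = z[g];
  double total = 0.0;
  std::vector<double> sum(S), sumsq(S);
  for (int k = 1; k <= K; ++k) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    int n = 0;
    for (int g = 0; g < G; ++g) {
      if (z[g] == k) {
        ++n;
        for (int s = 0; s < S; ++s) {
          double x = data(g, s);
          sum[s] += x;
          sumsq[s] += x * x;
        }
      }
    }
    for (int s = 0; s < S; ++s)
      total += blm_stats(n, sum[s], sumsq[s], mu0, lambda0, alpha0, beta0);
  }
  return total;
}
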