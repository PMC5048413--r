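// Felsenstein pruning over the 61 sense-codon states for a site-class
// mixture of GY94 models. Transition probabilities are built from cached
// spectral decompositions of each class-specific rate matrix; tip edges use
// column gathers instead of full matrix products. Per-pattern scaling keeps
// partial likelihoods in range on deep trees.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// states:   ntip x npat codon indices (1..61), 0 = missing (gap/N/stop)
// edge:     nedge x 2 (parent, child), postorder, nodes 1..nnode, tips first
// edgeLen:  nedge x nclass effective lengths (mixture classes share a
//           common per-branch scale, so class-specific lengths differ)
// edgeDecomp: nedge x nclass, 1-based index into the decomposition lists
// U, lam, Uinv: spectral decompositions, one per distinct (kappa, omega)
// Returns per-pattern log-likelihoods (mixture over classes).
// [[Rcpp::export]]
NumericVector codon_pruning_loglik(IntegerMatrix states,
                                   IntegerMatrix edge,
                                   NumericMatrix edgeLen,
                                   List U, List lam, List Uinv,
                                   IntegerMatrix edgeDecomp,
                                   NumericVector pi,
                                   NumericVector classWeights) {
  const int ntip = states.nrow();
  const int npat = states.ncol();
  const int nedge = edge.nrow();
  const int nclass = classWeights.size();
  const int nstate = pi.size();
  int nnode = 0;
  for (int e = 0; e < nedge; ++e) {
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  }
  const int root = edge(nedge - 1, 0) - 1;

  arma::rowvec piv(nstate);
  for (int s = 0; s < nstate; ++s) piv[s] = pi[s];

  // cache P matrices within this call, keyed by (decomp, edge length)
  std::vector<arma::mat> Pcache;
  std::vector<std::pair<int, double> > Pkey;
  arma::mat mix(nclass, npat);

  for (int c = 0; c < nclass; ++c) {
    std::vector<arma::mat> part(nnode);
    std::vector<bool> seen(nnode, false);
    arma::rowvec logscale(npat, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      const int d = edgeDecomp(e, c) - 1;
      const double t = edgeLen(e, c);

      int hit = -1;
      for (size_t k = 0; k < Pkey.size(); ++k)
        if (Pkey[k].first == d && Pkey[k].second == t) { hit = (int)k; break; }
      if (hit < 0) {
        arma::mat Ud = U[d];
        arma::vec ld = lam[d];
        arma::mat Vd = Uinv[d];
        arma::vec ex = arma::exp(ld * t);
        arma::mat P = Ud * (Vd.each_col() % ex);
        P.clamp(0.0, arma::datum::inf);
        Pcache.push_back(P);
        Pkey.push_back(std::make_pair(d, t));
        hit = (int)Pcache.size() - 1;
      }
      const arma::mat &P = Pcache[hit];

      arma::mat contrib(nstate, npat);
      if (child < ntip) {
        for (int p = 0; p < npat; ++p) {
          const int s = states(child, p);
          if (s > 0) {
            contrib.col(p) = P.col(s - 1);
          } else {
            contrib.col(p) = arma::sum(P, 1);  // missing tip: sum over states
          }
        }
      } else {
        contrib = P * part[child];
        part[child].reset();
      }
      if (!seen[parent]) {
        part[parent] = contrib;
        seen[parent] = true;
      } else {
        part[parent] %= contrib;
        // rescale to avoid underflow on deep trees
        arma::rowvec mx = arma::max(part[parent], 0);
        for (int p = 0; p < npat; ++p) {
          if (mx[p] > 0 && mx[p] < 1e-80) {
            part[parent].col(p) /= mx[p];
            logscale[p] += std::log(mx[p]);
          }
        }
      }
    }
    arma::rowvec site = piv * part[root];
    for (int p = 0; p < npat; ++p) {
      mix(c, p) = (site[p] > 0 ? std::log(site[p]) : -1e300) + logscale[p];
    }
  }

  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    double m = -1e300;
    for (int c = 0; c < nclass; ++c)
      m = std::max(m, mix(c, p) + std::log(classWeights[c]));
    double acc = 0.0;
    for (int c = 0; c < nclass; ++c)
      acc += std::exp(mix(c, p) + std::log(classWeights[c]) - m);
    out[p] = m + std::log(acc);
  }
  return out;
}
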