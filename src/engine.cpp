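#include <Rcpp.h>
using namespace Rcpp;

// Compiled intragenerational tick loop. Mirrors the R reference engine
// (step_tick) operation for operation, including the order of RNG draws:
// one unif_rand() per argmax tie, agents visited in id order. Neighborhood
// sums use a long double accumulator to match R's sum().

// [[Rcpp::export]]
List run_generation_cpp(IntegerVector loc, NumericVector biomass,
                        NumericVector alpha, NumericVector delta,
                        NumericVector rho, NumericVector R,
                        IntegerMatrix nbr, IntegerVector nnbr,
                        int n_ticks, double u, double h, double q,
                        double kappa, double cost,
                        double r, double s, double g,
                        bool self_excluded) {
  const int na = loc.size();
  const int nc = R.size();

  IntegerVector loc_ = clone(loc);
  NumericVector B = clone(biomass);
  NumericVector Res = clone(R);

  std::vector<int> J(nc), Nk(nc), newloc(na);
  std::vector<double> RM(nc), Fk(nc);
  std::vector<bool> stayed(na);
  std::vector<double> V(9);
  std::vector<int> ties(9);

  for (int t = 0; t < n_ticks; ++t) {
    // occupancy from current locations
    std::fill(J.begin(), J.end(), 0);
    for (int a = 0; a < na; ++a) J[loc_[a]]++;

    // neighborhood means of resources (occupancy means are per-agent when
    // the focal agent excludes itself from the perceived occupancy field)
    for (int k = 0; k < nc; ++k) {
      int m = nnbr[k];
      long double sr = 0.0L;
      for (int l = 0; l < m; ++l) sr += Res[nbr(k, l)];
      RM[k] = (double) sr / m;
    }

    // synchronous decisions
    for (int a = 0; a < na; ++a) {
      int k0 = loc_[a];
      int m = nnbr[k0];
      double al = alpha[a], de = delta[a], rh = rho[a];
      // occupancy as perceived by agent a: itself removed from its cell
      double self = self_excluded ? 1.0 : 0.0;
      for (int i = 0; i <= m; ++i) {
        int kk = (i == 0) ? k0 : nbr(k0, i - 1);
        int mm = nnbr[kk];
        long double sj = 0.0L;
        for (int l = 0; l < mm; ++l) {
          int kl = nbr(kk, l);
          sj += (double) J[kl] - (kl == k0 ? self : 0.0);
        }
        double Jk = (double) J[kk] - (kk == k0 ? self : 0.0);
        double JMk = (double) sj / mm;
        V[i] = Res[kk] - de * Jk + al * (RM[kk] - de * JMk);
      }
      bool stay = V[0] > 0.0;
      if (stay) {
        for (int l = 1; l <= m; ++l) {
          if (!(rh * V[l] < V[0])) { stay = false; break; }
        }
      }
      if (stay) {
        stayed[a] = true;
        newloc[a] = k0;
      } else {
        double vmax = V[0];
        for (int l = 1; l <= m; ++l) if (V[l] > vmax) vmax = V[l];
        int ntie = 0;
        for (int l = 0; l <= m; ++l) if (V[l] == vmax) ties[ntie++] = l;
        int pick = ties[0];
        if (ntie > 1) pick = ties[(int) std::floor(unif_rand() * ntie)];
        stayed[a] = false;
        newloc[a] = (pick == 0) ? k0 : nbr(k0, pick - 1);
      }
    }

    // extraction by stayers
    std::fill(Nk.begin(), Nk.end(), 0);
    for (int a = 0; a < na; ++a) if (stayed[a]) Nk[newloc[a]]++;
    for (int k = 0; k < nc; ++k) {
      if (Nk[k] > 0) {
        double share = Res[k] / (double) Nk[k];
        double functional = u * Res[k] / (h + Res[k] + q * (double) Nk[k]);
        Fk[k] = share < functional ? share : functional;
      } else Fk[k] = 0.0;
    }

    // biomass updates
    for (int a = 0; a < na; ++a) {
      if (stayed[a]) B[a] = B[a] + kappa * Fk[newloc[a]];
      else B[a] = (1.0 - cost) * B[a];
    }

    // resource extraction + renewal
    for (int k = 0; k < nc; ++k) {
      double rstar = Res[k] - (double) Nk[k] * Fk[k];
      if (rstar < 0.0) rstar = 0.0;  // rounding residue of the N*F <= R bound
      Res[k] = rstar + r * (1.0 - rstar / s) * (rstar + g);
    }

    for (int a = 0; a < na; ++a) loc_[a] = newloc[a];
  }

  return List::create(_["location"] = loc_, _["biomass"] = B, _["R"] = Res);
}
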