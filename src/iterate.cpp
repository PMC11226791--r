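#include <Rcpp.h>
using namespace Rcpp;

// One-generation update and long-run iteration of the two-locus
// pollen-killer recursion. Genotype order and gamete matrices are fixed by
// the caller; this loop only does the per-generation arithmetic:
//   pool  f = Gm' theta (normalized)
//   p_ij  = Gf[i,u] (Ms Gm[i,v] + Mp f[v]) / N_i  (+ mirrored term, u != v)
//   theta'_j = sum_i theta_i phi_i p_ij, renormalized.
// N_i and phi_i do not depend on theta, so they are precomputed here.
//
// Stop rule: terminate when the killer (Ab) haplotype frequency drops
// below thr_killer or the sensitive (aB) frequency below thr_sensitive
// (either may be <= 0 to disable), or after max_gen generations.
//
// [[Rcpp::export]]
List sd_iterate_cpp(NumericVector theta0, NumericMatrix Gf, NumericMatrix Gm,
                    IntegerVector h1, IntegerVector h2, NumericMatrix hapdose,
                    double Ms, double Mp, double R,
                    double thr_killer, double thr_sensitive,
                    int max_gen, bool record) {
  const int G = 10, H = 4;
  NumericVector theta = clone(theta0);

  // constants of the run
  NumericVector rowsum(G), N(G), phi(G);
  const double Mtot = Ms + Mp;
  for (int i = 0; i < G; ++i) {
    double rs = 0.0;
    for (int v = 0; v < H; ++v) rs += Gm(i, v);
    rowsum[i] = rs;
    N[i] = Mp + Ms * rs;
    double ph = N[i] * R / Mtot;
    phi[i] = (N[i] <= 0.0) ? 0.0 : (ph > 1.0 ? 1.0 : ph);
  }

  NumericMatrix traj;
  if (record) traj = NumericMatrix(max_gen + 1, G);

  NumericVector hap(H), f(H), tnew(G), W(G);
  int gen = 0;
  std::string stop_reason = "max_generations";
  bool extinct = false, degenerate = false;

  auto hapfreq = [&](const NumericVector& th) {
    for (int v = 0; v < H; ++v) {
      double a = 0.0;
      for (int i = 0; i < G; ++i) a += hapdose(i, v) * th[i];
      hap[v] = a;
    }
  };

  if (record) for (int j = 0; j < G; ++j) traj(0, j) = theta[j];

  hapfreq(theta);
  bool hit = (thr_killer > 0.0 && hap[1] < thr_killer) ||
             (thr_sensitive > 0.0 && hap[2] < thr_sensitive);
  if (hit) stop_reason = "threshold";

  while (!hit && gen < max_gen) {
    // pollen pool
    double tot = 0.0;
    for (int v = 0; v < H; ++v) {
      double m = 0.0;
      for (int i = 0; i < G; ++i) m += Gm(i, v) * theta[i];
      f[v] = m;
      tot += m;
    }
    if (tot > 0.0) {
      for (int v = 0; v < H; ++v) f[v] /= tot;
    } else if (Mp > 0.0) {
      degenerate = true;
      break;
    } else {
      for (int v = 0; v < H; ++v) f[v] = 0.0;
    }

    for (int i = 0; i < G; ++i)
      W[i] = (N[i] > 0.0) ? theta[i] * phi[i] / N[i] : 0.0;

    double tsum = 0.0;
    for (int j = 0; j < G; ++j) {
      const int u = h1[j], v = h2[j];
      double acc = 0.0;
      if (u == v) {
        for (int i = 0; i < G; ++i) {
          if (W[i] == 0.0) continue;
          acc += W[i] * Gf(i, u) * (Ms * Gm(i, u) + Mp * f[u]);
        }
      } else {
        for (int i = 0; i < G; ++i) {
          if (W[i] == 0.0) continue;
          acc += W[i] * (Gf(i, u) * (Ms * Gm(i, v) + Mp * f[v]) +
                         Gf(i, v) * (Ms * Gm(i, u) + Mp * f[u]));
        }
      }
      tnew[j] = acc;
      tsum += acc;
    }
    if (tsum <= 0.0) { extinct = true; break; }
    for (int j = 0; j < G; ++j) {
      double x = tnew[j] / tsum;
      theta[j] = (x < 0.0 && x > -1e-12) ? 0.0 : x;
    }
    ++gen;
    if (record) for (int j = 0; j < G; ++j) traj(gen, j) = theta[j];

    hapfreq(theta);
    hit = (thr_killer > 0.0 && hap[1] < thr_killer) ||
          (thr_sensitive > 0.0 && hap[2] < thr_sensitive);
    if (hit) stop_reason = "threshold";
  }

  List out = List::create(
    _["theta"] = theta,
    _["generations"] = gen,
    _["stop_reason"] = stop_reason,
    _["extinct"] = extinct,
    _["degenerate"] = degenerate);
  if (record) {
    out["trajectory"] = traj(Range(0, gen), _);
  }
  return out;
}
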