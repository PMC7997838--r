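#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler integration of a pathway network driven by an
// exogenous biomass forcing sampled on the same grid.
//
// Fully explicit scheme: every reaction rate is evaluated on the pre-step
// state vector; consumption uses the substrate's own concentration,
// production the upstream substrate's. Stoichiometry is 1:1 molar, so each
// reaction removes r from its substrate and (when a product exists) adds the
// same r to its product.
//
// s0    initial concentrations (umol/l), one per compound
// x     biomass (mg/l) at every grid point 0..n_steps (length n_steps + 1)
// sub   1-based substrate index per reaction
// prod  1-based product index per reaction, 0 = terminal sink
// inhib 1-based inhibitor index per reaction, 0 = first-order law
// keep  sorted 1-based grid rows to return (row 1 = t = 0)
// clip  clip components driven below zero back to zero after each step
//
// Inputs are copied into plain arrays before the time loop: the loop runs
// millions of times inside a fit and must not touch R memory.
//
// [[Rcpp::export]]
List euler_core(NumericVector s0, NumericVector x, double dt,
                IntegerVector sub, IntegerVector prod, IntegerVector inhib,
                NumericVector k, NumericVector ki,
                IntegerVector keep, bool clip) {
  const int nc = s0.size(), nr = sub.size(), nkeep = keep.size();
  const int nstep = x.size() - 1;
  std::vector<double> s(s0.begin(), s0.end()), d(nc);
  const std::vector<double> xv(x.begin(), x.end()), kv(k.begin(), k.end()),
      kiv(ki.begin(), ki.end());
  std::vector<int> sb(nr), pr(nr), ih(nr), kp(nkeep);
  for (int j = 0; j < nr; ++j) {
    sb[j] = sub[j] - 1;
    pr[j] = prod[j] - 1;   // -1 = terminal sink
    ih[j] = inhib[j] - 1;  // -1 = first-order
  }
  for (int i = 0; i < nkeep; ++i) kp[i] = keep[i] - 1;
  NumericMatrix out(nkeep, nc);
  int kpos = 0, nclip = 0;
  for (int step = 0; step <= nstep; ++step) {
    while (kpos < nkeep && kp[kpos] == step) {
      for (int i = 0; i < nc; ++i) out(kpos, i) = s[i];
      ++kpos;
    }
    if (step == nstep) break;
    for (int i = 0; i < nc; ++i) d[i] = 0.0;
    for (int j = 0; j < nr; ++j) {
      double r = kv[j] * s[sb[j]];
      if (ih[j] >= 0) r *= kiv[j] / (kiv[j] + s[ih[j]]);
      d[sb[j]] -= r;
      if (pr[j] >= 0) d[pr[j]] += r;
    }
    const double f = dt * xv[step];
    for (int i = 0; i < nc; ++i) {
      s[i] += f * d[i];
      if (s[i] < 0.0) {
        if (clip) s[i] = 0.0;
        ++nclip;
      }
    }
  }
  return List::create(_["conc"] = out, _["n_clipped"] = nclip);
}
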