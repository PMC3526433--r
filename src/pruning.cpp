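#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns under K80.
//
// edge:   (nedge) x 2 integer matrix of (parent, child) node indices
//         (1-based), rows in postorder so every child row precedes the
//         row in which its parent appears as a child.
// pvals:  nedge x 3 matrix of (psame, pti, ptv) per edge row.
// tiprow: length-nnode integer vector; for tip nodes the (1-based)
//         column of patT holding that tip's states, 0 for internal.
// patT:   npat x ntaxa integer matrix of IUPAC bitmasks, one column per
//         taxon (A=1, C=2, G=4, T=8; anything outside 1..15 = missing).
// root:   index of the root node.
//
// Returns per-pattern log-likelihoods with uniform (1/4) root
// frequencies. Partials are stored per state as contiguous pattern
// vectors (structure-of-arrays); tip edges go through a 16-entry
// bitmask lookup table instead of explicit partial vectors. The
// transition partner of state a (base order A, C, G, T) is (a XOR 2).
// [[Rcpp::export]]
NumericVector pruning_pattern_loglik(IntegerMatrix edge, NumericMatrix pvals,
                                     int nnode, IntegerVector tiprow,
                                     IntegerMatrix patT, int root) {
  const int npat = patT.nrow();
  const int nedge = edge.nrow();

  static std::vector<double> part;
  static std::vector<double> logscale;
  static std::vector<double> vbuf;
  const size_t needed = (size_t)nnode * 4 * npat;
  if (part.size() < needed) part.resize(needed);
  logscale.assign(npat, 0.0);
  if (vbuf.size() < (size_t)4 * npat) vbuf.resize((size_t)4 * npat);
  std::vector<char> seen(nnode, 0);

  double *v0 = vbuf.data(), *v1 = v0 + npat, *v2 = v1 + npat,
         *v3 = v2 + npat;

  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double ps = pvals(e, 0), pi = pvals(e, 1), pv = pvals(e, 2);
    const double ds = ps - pv, di = pi - pv;
    const int trow = tiprow[c];
    if (trow > 0) {
      // tip child: per-bitmask lookup table, lut[a][m]
      double lut0[16], lut1[16], lut2[16], lut3[16];
      for (int m = 1; m < 16; ++m) {
        const double b0 = m & 1, b1 = (m >> 1) & 1, b2 = (m >> 2) & 1,
                     b3 = (m >> 3) & 1;
        const double tot = pv * (b0 + b1 + b2 + b3);
        lut0[m] = tot + ds * b0 + di * b2;
        lut1[m] = tot + ds * b1 + di * b3;
        lut2[m] = tot + ds * b2 + di * b0;
        lut3[m] = tot + ds * b3 + di * b1;
      }
      lut0[0] = lut0[15]; lut1[0] = lut1[15]; lut2[0] = lut2[15];
      lut3[0] = lut3[15];
      const int *code = &patT(0, trow - 1);
      for (int s = 0; s < npat; ++s) {
        int m = code[s];
        if (m < 0 || m > 15) m = 15;
        v0[s] = lut0[m]; v1[s] = lut1[m]; v2[s] = lut2[m]; v3[s] = lut3[m];
      }
    } else {
      const double *cp = &part[(size_t)c * 4 * npat];
      const double *c0 = cp, *c1 = cp + npat, *c2 = cp + 2 * npat,
                   *c3 = cp + 3 * npat;
      for (int s = 0; s < npat; ++s) {
        const double tot = pv * (c0[s] + c1[s] + c2[s] + c3[s]);
        v0[s] = tot + ds * c0[s] + di * c2[s];
        v1[s] = tot + ds * c1[s] + di * c3[s];
        v2[s] = tot + ds * c2[s] + di * c0[s];
        v3[s] = tot + ds * c3[s] + di * c1[s];
      }
    }
    double *pp = &part[(size_t)p * 4 * npat];
    double *q0 = pp, *q1 = pp + npat, *q2 = pp + 2 * npat,
           *q3 = pp + 3 * npat;
    if (!seen[p]) {
      seen[p] = 1;
      for (int s = 0; s < npat; ++s) {
        q0[s] = v0[s]; q1[s] = v1[s]; q2[s] = v2[s]; q3[s] = v3[s];
      }
    } else {
      for (int s = 0; s < npat; ++s) {
        q0[s] *= v0[s]; q1[s] *= v1[s]; q2[s] *= v2[s]; q3[s] *= v3[s];
        double mx = q0[s] > q1[s] ? q0[s] : q1[s];
        if (q2[s] > mx) mx = q2[s];
        if (q3[s] > mx) mx = q3[s];
        if (mx < 1e-240 && mx > 0.0) {
          const double f = 1e240;
          q0[s] *= f; q1[s] *= f; q2[s] *= f; q3[s] *= f;
          logscale[s] += std::log(1e-240);
        }
      }
    }
  }

  NumericVector out(npat);
  const double *rp = &part[(size_t)(root - 1) * 4 * npat];
  for (int s = 0; s < npat; ++s) {
    const double lik = 0.25 * (rp[s] + rp[npat + s] + rp[2 * npat + s] +
                               rp[3 * npat + s]);
    out[s] = std::log(lik) + logscale[s];
  }
  return out;
}

// ---------------------------------------------------------------------
// Per-branch ML optimization of a tree on one pattern set (one gene, or
// pooled genes) under K80: coordinate ascent with partial-likelihood
// profiling. For the branch under optimization the likelihood is
//   L_s(t) = sum_ab F[a,s] P_ab(t) G[b,s]
//          = ptv*SF*SG + (psame-ptv)*dot(F,G) + (pti-ptv)*dotx(F,G)
// so each golden-section step costs three multiplies and a log per
// pattern. Sweeps run in preorder with fresh above-partials and
// below-partials recomputed between sweeps.
// ---------------------------------------------------------------------

static inline void k80_p(double t, double alpha, double beta,
                         double &ps, double &pi, double &pv) {
  const double e1 = std::exp(-4.0 * beta * t);
  const double e2 = std::exp(-2.0 * (alpha + beta) * t);
  ps = 0.25 + 0.25 * e1 + 0.5 * e2;
  pi = 0.25 + 0.25 * e1 - 0.5 * e2;
  pv = 0.25 - 0.25 * e1;
}

// [[Rcpp::export]]
List pruning_optimize_branches(IntegerMatrix edge, NumericVector lens0,
                               int nnode, IntegerVector tiprow,
                               IntegerMatrix patT, IntegerVector patsel,
                               NumericVector wt, int root,
                               double alpha, double beta,
                               int sweeps, int iters) {
  const int np = patsel.size();
  const int nedge = edge.nrow();
  std::vector<double> lens(lens0.begin(), lens0.end());
  std::vector<double> part((size_t)nnode * 4 * np);
  std::vector<double> PD((size_t)nedge * 4 * np);
  std::vector<double> F((size_t)nedge * 4 * np);
  std::vector<char> isTip(nnode, 0);

  // children edges per node; incoming edge per node
  std::vector<std::vector<int> > kids(nnode);
  std::vector<int> inc(nnode, -1);
  for (int e = 0; e < nedge; ++e) {
    kids[edge(e, 0) - 1].push_back(e);
    inc[edge(e, 1) - 1] = e;
  }

  // tip partials (fixed)
  for (int v = 0; v < nnode; ++v) {
    if (tiprow[v] <= 0) continue;
    isTip[v] = 1;
    double *pv_ = &part[(size_t)v * 4 * np];
    for (int s = 0; s < np; ++s) {
      int code = patT(patsel[s] - 1, tiprow[v] - 1);
      if (code <= 0 || code > 15) code = 15;
      pv_[0 * np + s] = code & 1 ? 1.0 : 0.0;
      pv_[1 * np + s] = code & 2 ? 1.0 : 0.0;
      pv_[2 * np + s] = code & 4 ? 1.0 : 0.0;
      pv_[3 * np + s] = code & 8 ? 1.0 : 0.0;
    }
  }

  // PD[e] = P(t_e) part[child(e)]
  auto updPD = [&](int e) {
    double ps, pi, pv;
    k80_p(lens[e], alpha, beta, ps, pi, pv);
    const double ds = ps - pv, di = pi - pv;
    const double *cp = &part[(size_t)(edge(e, 1) - 1) * 4 * np];
    double *out = &PD[(size_t)e * 4 * np];
    for (int s = 0; s < np; ++s) {
      const double c0 = cp[s], c1 = cp[np + s], c2 = cp[2 * np + s],
                   c3 = cp[3 * np + s];
      const double tot = pv * (c0 + c1 + c2 + c3);
      out[s] = tot + ds * c0 + di * c2;
      out[np + s] = tot + ds * c1 + di * c3;
      out[2 * np + s] = tot + ds * c2 + di * c0;
      out[3 * np + s] = tot + ds * c3 + di * c1;
    }
  };

  // recompute below-partials (postorder = edge row order)
  auto computeD = [&]() {
    std::vector<char> seen(nnode, 0);
    for (int e = 0; e < nedge; ++e) {
      updPD(e);
      int p = edge(e, 0) - 1;
      double *pp = &part[(size_t)p * 4 * np];
      const double *pd = &PD[(size_t)e * 4 * np];
      if (!seen[p]) {
        seen[p] = 1;
        std::copy(pd, pd + 4 * (size_t)np, pp);
      } else {
        for (size_t i = 0; i < 4 * (size_t)np; ++i) pp[i] *= pd[i];
      }
    }
  };

  auto rootLoglik = [&]() {
    const double *rp = &part[(size_t)(root - 1) * 4 * np];
    double ll = 0.0;
    for (int s = 0; s < np; ++s) {
      ll += wt[s] * std::log(0.25 * (rp[s] + rp[np + s] + rp[2 * np + s] +
                                     rp[3 * np + s]));
    }
    return ll;
  };

  computeD();
  double cur = rootLoglik();
  const double invphi = 0.6180339887498949;

  std::function<void(int)> sweepNode = [&](int v) {
    for (size_t ki = 0; ki < kids[v].size(); ++ki) {
      int e = kids[v][ki];
      int c = edge(e, 1) - 1;
      // F_e = (above partial at v) * prod of sibling PDs
      double *fe = &F[(size_t)e * 4 * np];
      if (inc[v] < 0) {
        for (size_t i = 0; i < 4 * (size_t)np; ++i) fe[i] = 0.25;
      } else {
        // A_v[b,s] = sum_a F_f[a,s] P_f[a,b] (P symmetric)
        int f = inc[v];
        double ps, pi, pv;
        k80_p(lens[f], alpha, beta, ps, pi, pv);
        const double ds = ps - pv, di = pi - pv;
        const double *ff = &F[(size_t)f * 4 * np];
        for (int s = 0; s < np; ++s) {
          const double f0 = ff[s], f1 = ff[np + s], f2 = ff[2 * np + s],
                       f3 = ff[3 * np + s];
          const double tot = pv * (f0 + f1 + f2 + f3);
          fe[s] = tot + ds * f0 + di * f2;
          fe[np + s] = tot + ds * f1 + di * f3;
          fe[2 * np + s] = tot + ds * f2 + di * f0;
          fe[3 * np + s] = tot + ds * f3 + di * f1;
        }
      }
      for (size_t kj = 0; kj < kids[v].size(); ++kj) {
        if (kj == ki) continue;
        const double *pd = &PD[(size_t)kids[v][kj] * 4 * np];
        for (size_t i = 0; i < 4 * (size_t)np; ++i) fe[i] *= pd[i];
      }
      // profile coefficients per pattern
      const double *gc = &part[(size_t)c * 4 * np];
      std::vector<double> sfsg(np), dot(np), dotx(np);
      for (int s = 0; s < np; ++s) {
        const double f0 = fe[s], f1 = fe[np + s], f2 = fe[2 * np + s],
                     f3 = fe[3 * np + s];
        const double g0 = gc[s], g1 = gc[np + s], g2 = gc[2 * np + s],
                     g3 = gc[3 * np + s];
        sfsg[s] = (f0 + f1 + f2 + f3) * (g0 + g1 + g2 + g3);
        dot[s] = f0 * g0 + f1 * g1 + f2 * g2 + f3 * g3;
        dotx[s] = f0 * g2 + f1 * g3 + f2 * g0 + f3 * g1;
      }
      auto evalt = [&](double t) {
        double ps, pi, pv;
        k80_p(t, alpha, beta, ps, pi, pv);
        const double ds = ps - pv, di = pi - pv;
        double ll = 0.0;
        for (int s = 0; s < np; ++s) {
          ll += wt[s] * std::log(pv * sfsg[s] + ds * dot[s] + di * dotx[s]);
        }
        return ll;
      };
      // golden-section maximization on [lo, hi]
      double lo = 1e-8, hi = 5.0;
      double x1 = hi - invphi * (hi - lo), x2 = lo + invphi * (hi - lo);
      double f1v = evalt(x1), f2v = evalt(x2);
      for (int it = 0; it < iters; ++it) {
        if (f1v < f2v) {
          lo = x1; x1 = x2; f1v = f2v;
          x2 = lo + invphi * (hi - lo); f2v = evalt(x2);
        } else {
          hi = x2; x2 = x1; f2v = f1v;
          x1 = hi - invphi * (hi - lo); f1v = evalt(x1);
        }
      }
      const double tbest = (f1v > f2v) ? x1 : x2;
      const double lbest = (f1v > f2v) ? f1v : f2v;
      if (lbest > evalt(lens[e])) lens[e] = tbest;
      updPD(e);
      if (!isTip[c]) sweepNode(c);
    }
  };

  for (int s = 0; s < sweeps; ++s) {
    sweepNode(root - 1);
    computeD();
    double nl = rootLoglik();
    if (nl - cur < 1e-3 && s > 0) { cur = std::max(cur, nl); break; }
    cur = std::max(cur, nl);
  }

  return List::create(Named("loglik") = cur,
                      Named("lengths") = NumericVector(lens.begin(),
                                                       lens.end()));
}
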