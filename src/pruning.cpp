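#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning for the Jukes-Cantor model with a discrete-rate
// mixture (categories passed as already-scaled rate multipliers) and an
// optional zero-rate invariant class.
//
// Node ids are 1-based: tips 1..ntip, internal ntip+1..nnode. `edge` holds
// (parent, child) rows in postorder. `tip_pat` is ntip x npat with base
// codes 0..3. `const_state` is -1 for variable patterns, else the base
// code of the constant pattern.
//
// JC transition along an edge of length t at rate r acts on a partial
// vector v as (P v)_x = e * v_x + (1 - e)/4 * sum(v), e = exp(-4 r t / 3).
//
// Per-node rescaling keeps partials in range; accumulated log scale is
// carried per pattern and category.

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// total and per-pattern log-likelihood by one postorder pass per category
// [[Rcpp::export]]
List cpp_pruning(IntegerMatrix edge, NumericVector edge_len, int ntip,
                 IntegerMatrix tip_pat, NumericVector rates,
                 double pinv, IntegerVector const_state,
                 NumericVector pat_w) {
  const int nedge = edge.nrow();
  const int npat = tip_pat.ncol();
  const int ncat = rates.size();
  int nnode = ntip;
  for (int k = 0; k < nedge; ++k) {
    if (edge(k, 0) > nnode) nnode = edge(k, 0);
    if (edge(k, 1) > nnode) nnode = edge(k, 1);
  }
  const int root = edge(nedge - 1, 0);

  std::vector<int> n_children(nnode + 1, 0), seen(nnode + 1, 0);
  for (int k = 0; k < nedge; ++k) n_children[edge(k, 0)]++;

  std::vector<double> down((size_t)(nnode - ntip) * npat * 4);
  std::vector<double> dscale((size_t)(nnode - ntip) * npat);
  NumericMatrix logsite(npat, ncat);

  for (int k = 0; k < ncat; ++k) {
    std::fill(down.begin(), down.end(), 1.0);
    std::fill(dscale.begin(), dscale.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0), c = edge(e, 1);
      const size_t pb = (size_t)(p - ntip - 1);
      const double ee = std::exp(-4.0 * rates[k] * edge_len[e] / 3.0);
      const double pdiff = (1.0 - ee) / 4.0;
      for (int i = 0; i < npat; ++i) {
        double w[4];
        if (c <= ntip) {
          const int s = tip_pat(c - 1, i);
          w[0] = w[1] = w[2] = w[3] = pdiff;
          w[s] += ee;
        } else {
          const double* v = &down[((size_t)(c - ntip - 1) * npat + i) * 4];
          const double S = v[0] + v[1] + v[2] + v[3];
          const double b = pdiff * S;
          w[0] = ee * v[0] + b; w[1] = ee * v[1] + b;
          w[2] = ee * v[2] + b; w[3] = ee * v[3] + b;
          dscale[pb * npat + i] += dscale[(size_t)(c - ntip - 1) * npat + i];
        }
        double* tgt = &down[(pb * npat + i) * 4];
        tgt[0] *= w[0]; tgt[1] *= w[1]; tgt[2] *= w[2]; tgt[3] *= w[3];
      }
      if (++seen[p] == n_children[p]) {  // node complete: rescale
        for (int i = 0; i < npat; ++i) {
          double* v = &down[(pb * npat + i) * 4];
          double m = v[0];
          if (v[1] > m) m = v[1];
          if (v[2] > m) m = v[2];
          if (v[3] > m) m = v[3];
          if (m > 0 && m != 1.0) {
            v[0] /= m; v[1] /= m; v[2] /= m; v[3] /= m;
            dscale[pb * npat + i] += std::log(m);
          }
        }
      }
    }
    const size_t rb = (size_t)(root - ntip - 1);
    for (int i = 0; i < npat; ++i) {
      const double* v = &down[(rb * npat + i) * 4];
      const double L = 0.25 * (v[0] + v[1] + v[2] + v[3]);
      logsite(i, k) = (L > 0 ? std::log(L) : R_NegInf) + dscale[rb * npat + i];
    }
  }

  // mix categories + invariant class
  NumericVector site_ll(npat);
  const double logmix = std::log((1.0 - pinv) / ncat);
  const double loginv = pinv > 0 ? std::log(pinv * 0.25) : R_NegInf;
  double total = 0.0;
  for (int i = 0; i < npat; ++i) {
    double M = R_NegInf;
    for (int k = 0; k < ncat; ++k) if (logsite(i, k) > M) M = logsite(i, k);
    double a;
    if (M == R_NegInf) a = R_NegInf;
    else {
      double s = 0.0;
      for (int k = 0; k < ncat; ++k) s += std::exp(logsite(i, k) - M);
      a = (pinv < 1.0) ? M + std::log(s) + logmix : R_NegInf;
    }
    double ll = a;
    if (pinv > 0 && const_state[i] >= 0) ll = logaddexp(a, loginv);
    site_ll[i] = ll;
    total += pat_w[i] * ll;
  }
  return List::create(_["loglik"] = total, _["site_loglik"] = site_ll);
}

// classic Brent minimization (golden section + successive parabolic
// interpolation) on [ax, bx]
static double brent_min(double ax, double bx,
                        double (*f)(double, void*), void* info,
                        double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(2.220446049250313e-16);
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  for (int iter = 0; iter < 200; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = eps * std::fabs(x) + tol / 3.0;
    const double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {  // try parabolic fit
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      const double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x < xm) ? b - x : a - x;
      d = c * e;
    }
    const double u = (std::fabs(d) >= tol1) ? x + d
                                            : x + ((d > 0) ? tol1 : -tol1);
    const double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

// negated profile log-likelihood in a single edge length t, given the
// per-pattern per-category decomposition A = sum_x F_x G_x,
// B = sum(F) sum(G) and accumulated log scale S (category-major layout:
// index k * npat + i): the per-category site likelihood at length t is
// e A + (1 - e)/4 B with e = exp(-4 r t / 3)
struct EdgeProfile {
  const double *A, *B, *S, *w;
  const int* cs;
  int npat, ncat;
  double pinv;
  const double* rates;
};

static double neg_profile(double t, void* info) {
  const EdgeProfile* ep = (const EdgeProfile*)info;
  const int npat = ep->npat, ncat = ep->ncat;
  double ee[16], pd[16];
  for (int k = 0; k < ncat && k < 16; ++k) {
    ee[k] = std::exp(-4.0 * ep->rates[k] * t / 3.0);
    pd[k] = (1.0 - ee[k]) / 4.0;
  }
  const double logmix = std::log((1.0 - ep->pinv) / ncat);
  const double loginv = ep->pinv > 0 ? std::log(ep->pinv * 0.25) : R_NegInf;
  double total = 0.0;
  for (int i = 0; i < npat; ++i) {
    double M = R_NegInf, ls[16];
    for (int k = 0; k < ncat && k < 16; ++k) {
      const double L = ep->A[(size_t)k * npat + i] * ee[k] +
                       ep->B[(size_t)k * npat + i] * pd[k];
      ls[k] = (L > 0 ? std::log(L) : R_NegInf) + ep->S[(size_t)k * npat + i];
      if (ls[k] > M) M = ls[k];
    }
    double a;
    if (M == R_NegInf) a = R_NegInf;
    else {
      double s = 0.0;
      for (int k = 0; k < ncat && k < 16; ++k) s += std::exp(ls[k] - M);
      a = M + std::log(s) + logmix;
    }
    double ll = a;
    if (ep->pinv > 0 && ep->cs[i] >= 0) ll = logaddexp(a, loginv);
    total += ep->w[i] * ll;
  }
  return -total;
}

// Full branch-length optimization: repeated sweeps, each one postorder
// (down) pass plus one preorder (up) pass during which every edge (or the
// subset in opt_edges) is Brent-optimized against the others' current
// lengths, with the edge's outgoing message refreshed immediately so later
// edges in the same sweep see the update. Sweeps stop when the
// log-likelihood improves by < tol. Category-blocked storage keeps all
// rate categories available at every edge visit. A sweep that fails to
// improve is reverted, so the returned log-likelihood never decreases
// across sweeps. From the second sweep on, the Brent bracket is narrowed
// around the edge's current value (its optimum only refines once the
// topology is fixed).
// [[Rcpp::export]]
List cpp_optimize_blens(IntegerMatrix edge, NumericVector edge_len, int ntip,
                        IntegerMatrix tip_pat, NumericVector rates,
                        double pinv, IntegerVector const_state,
                        NumericVector pat_w, double min_bl, double max_bl,
                        int max_sweeps, double tol, IntegerVector opt_edges) {
  const int nedge = edge.nrow();
  const int npat = tip_pat.ncol();
  const int ncat = rates.size();
  int nnode = ntip;
  for (int k = 0; k < nedge; ++k) {
    if (edge(k, 0) > nnode) nnode = edge(k, 0);
    if (edge(k, 1) > nnode) nnode = edge(k, 1);
  }
  const int root = edge(nedge - 1, 0);
  const int nint = nnode - ntip;

  std::vector<int> n_children(nnode + 1, 0), seen(nnode + 1, 0);
  for (int k = 0; k < nedge; ++k) n_children[edge(k, 0)]++;

  // restrict Brent to a subset of edges (1-based); empty = all edges
  std::vector<bool> optimize_edge(nedge, true);
  if (opt_edges.size() > 0) {
    std::fill(optimize_edge.begin(), optimize_edge.end(), false);
    for (int k = 0; k < opt_edges.size(); ++k)
      if (opt_edges[k] >= 1 && opt_edges[k] <= nedge)
        optimize_edge[opt_edges[k] - 1] = true;
  }

  // category-blocked arrays
  std::vector<double> down((size_t)nint * ncat * npat * 4);
  std::vector<double> dscale((size_t)nint * ncat * npat);
  std::vector<double> msg((size_t)nedge * ncat * npat * 4);
  std::vector<double> up((size_t)nint * ncat * npat * 4);
  std::vector<double> uscale((size_t)nint * ncat * npat);
  std::vector<double> H((size_t)ncat * npat * 4), Hs((size_t)ncat * npat);
  std::vector<double> A((size_t)ncat * npat), B((size_t)ncat * npat),
      S((size_t)ncat * npat);
  std::vector<double> el(edge_len.begin(), edge_len.end());

  const double logmix = std::log((1.0 - pinv) / ncat);
  const double loginv = pinv > 0 ? std::log(pinv * 0.25) : R_NegInf;

  #define DOWN(nb, k, i) (&down[(((size_t)(nb) * ncat + (k)) * npat + (i)) * 4])
  #define DSC(nb, k, i) (dscale[((size_t)(nb) * ncat + (k)) * npat + (i)])
  #define MSG(e, k, i) (&msg[(((size_t)(e) * ncat + (k)) * npat + (i)) * 4])
  #define UP(nb, k, i) (&up[(((size_t)(nb) * ncat + (k)) * npat + (i)) * 4])
  #define USC(nb, k, i) (uscale[((size_t)(nb) * ncat + (k)) * npat + (i)])

  EdgeProfile ep;
  ep.w = pat_w.begin(); ep.cs = const_state.begin();
  ep.npat = npat; ep.ncat = ncat;
  ep.pinv = pinv; ep.rates = rates.begin();

  std::vector<double> logsite((size_t)ncat * npat);

  // one postorder pass at the current lengths; fills down/dscale/msg and
  // returns the total log-likelihood
  auto down_pass = [&]() -> double {
    std::fill(down.begin(), down.end(), 1.0);
    std::fill(dscale.begin(), dscale.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0), c = edge(e, 1);
      const int pb = p - ntip - 1;
      for (int k = 0; k < ncat; ++k) {
        const double ee = std::exp(-4.0 * rates[k] * el[e] / 3.0);
        const double pdiff = (1.0 - ee) / 4.0;
        for (int i = 0; i < npat; ++i) {
          double* mm = MSG(e, k, i);
          if (c <= ntip) {
            const int s = tip_pat(c - 1, i);
            mm[0] = mm[1] = mm[2] = mm[3] = pdiff;
            mm[s] += ee;
          } else {
            const double* v = DOWN(c - ntip - 1, k, i);
            const double Sv = v[0] + v[1] + v[2] + v[3];
            const double b = pdiff * Sv;
            mm[0] = ee * v[0] + b; mm[1] = ee * v[1] + b;
            mm[2] = ee * v[2] + b; mm[3] = ee * v[3] + b;
            DSC(pb, k, i) += DSC(c - ntip - 1, k, i);
          }
          double* tgt = DOWN(pb, k, i);
          tgt[0] *= mm[0]; tgt[1] *= mm[1]; tgt[2] *= mm[2]; tgt[3] *= mm[3];
        }
      }
      if (++seen[p] == n_children[p]) {
        for (int k = 0; k < ncat; ++k)
          for (int i = 0; i < npat; ++i) {
            double* v = DOWN(pb, k, i);
            double m = v[0];
            if (v[1] > m) m = v[1];
            if (v[2] > m) m = v[2];
            if (v[3] > m) m = v[3];
            if (m > 0 && m != 1.0) {
              v[0] /= m; v[1] /= m; v[2] /= m; v[3] /= m;
              DSC(pb, k, i) += std::log(m);
            }
          }
      }
    }
    const int rb = root - ntip - 1;
    double total = 0.0;
    for (int i = 0; i < npat; ++i) {
      double M = R_NegInf;
      for (int k = 0; k < ncat; ++k) {
        const double* v = DOWN(rb, k, i);
        const double L = 0.25 * (v[0] + v[1] + v[2] + v[3]);
        const double lsk = (L > 0 ? std::log(L) : R_NegInf) + DSC(rb, k, i);
        logsite[(size_t)k * npat + i] = lsk;
        if (lsk > M) M = lsk;
      }
      double a;
      if (M == R_NegInf) a = R_NegInf;
      else {
        double s = 0.0;
        for (int k = 0; k < ncat; ++k)
          s += std::exp(logsite[(size_t)k * npat + i] - M);
        a = M + std::log(s) + logmix;
      }
      double ll = a;
      if (pinv > 0 && const_state[i] >= 0) ll = logaddexp(a, loginv);
      total += pat_w[i] * ll;
    }
    return total;
  };

  double ll = down_pass();
  int sweeps = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    ++sweeps;
    std::vector<double> el_before(el);
    // up pass with in-place edge optimization
    const int rb = root - ntip - 1;
    for (int k = 0; k < ncat; ++k)
      for (int i = 0; i < npat; ++i) {
        double* u = UP(rb, k, i);
        u[0] = u[1] = u[2] = u[3] = 0.25;
        USC(rb, k, i) = 0.0;
      }
    for (int e = nedge - 1; e >= 0; --e) {
      const int p = edge(e, 0), c = edge(e, 1);
      const int pb = p - ntip - 1;
      const bool do_opt = optimize_edge[e];
      if (!do_opt && c <= ntip) continue;
      // H = up[p] * prod of sibling messages
      for (int k = 0; k < ncat; ++k)
        for (int i = 0; i < npat; ++i) {
          const double* u = UP(pb, k, i);
          double* h = &H[((size_t)k * npat + i) * 4];
          h[0] = u[0]; h[1] = u[1]; h[2] = u[2]; h[3] = u[3];
          Hs[(size_t)k * npat + i] = USC(pb, k, i);
        }
      for (int e2 = 0; e2 < nedge; ++e2) {
        if (e2 == e || edge(e2, 0) != p) continue;
        const int c2 = edge(e2, 1);
        for (int k = 0; k < ncat; ++k)
          for (int i = 0; i < npat; ++i) {
            const double* mm = MSG(e2, k, i);
            double* h = &H[((size_t)k * npat + i) * 4];
            h[0] *= mm[0]; h[1] *= mm[1]; h[2] *= mm[2]; h[3] *= mm[3];
            if (c2 > ntip)
              Hs[(size_t)k * npat + i] += DSC(c2 - ntip - 1, k, i);
          }
      }
      if (do_opt) {
        // profile arrays for this edge
        for (int k = 0; k < ncat; ++k)
          for (int i = 0; i < npat; ++i) {
            double Fv[4];
            double fscale = 0.0;
            if (c <= ntip) {
              Fv[0] = Fv[1] = Fv[2] = Fv[3] = 0.0;
              Fv[tip_pat(c - 1, i)] = 1.0;
            } else {
              const double* v = DOWN(c - ntip - 1, k, i);
              Fv[0] = v[0]; Fv[1] = v[1]; Fv[2] = v[2]; Fv[3] = v[3];
              fscale = DSC(c - ntip - 1, k, i);
            }
            const double* h = &H[((size_t)k * npat + i) * 4];
            const size_t ix = (size_t)k * npat + i;
            A[ix] = Fv[0] * h[0] + Fv[1] * h[1] + Fv[2] * h[2] + Fv[3] * h[3];
            B[ix] = (Fv[0] + Fv[1] + Fv[2] + Fv[3]) *
                    (h[0] + h[1] + h[2] + h[3]);
            S[ix] = Hs[ix] + fscale;
          }
        ep.A = A.data(); ep.B = B.data(); ep.S = S.data();
        double lo = min_bl, hi = max_bl;
        if (sweep > 0) {  // refine around the current value
          lo = std::max(min_bl, el[e] / 8.0);
          hi = std::min(max_bl, std::max(el[e] * 8.0, el[e] + 0.05));
        }
        const double t_new = brent_min(lo, hi, neg_profile, &ep, 1e-6);
        if (-neg_profile(t_new, &ep) > -neg_profile(el[e], &ep)) el[e] = t_new;
        // refresh this edge's message at the (possibly) new length
        for (int k = 0; k < ncat; ++k) {
          const double ee = std::exp(-4.0 * rates[k] * el[e] / 3.0);
          const double pdiff = (1.0 - ee) / 4.0;
          for (int i = 0; i < npat; ++i) {
            double* mm = MSG(e, k, i);
            if (c <= ntip) {
              const int s = tip_pat(c - 1, i);
              mm[0] = mm[1] = mm[2] = mm[3] = pdiff;
              mm[s] += ee;
            } else {
              const double* v = DOWN(c - ntip - 1, k, i);
              const double Sv = v[0] + v[1] + v[2] + v[3];
              const double b = pdiff * Sv;
              mm[0] = ee * v[0] + b; mm[1] = ee * v[1] + b;
              mm[2] = ee * v[2] + b; mm[3] = ee * v[3] + b;
            }
          }
        }
      }
      // propagate up partials through this edge
      if (c > ntip) {
        const int cb = c - ntip - 1;
        for (int k = 0; k < ncat; ++k) {
          const double ee = std::exp(-4.0 * rates[k] * el[e] / 3.0);
          const double pdiff = (1.0 - ee) / 4.0;
          for (int i = 0; i < npat; ++i) {
            const double* h = &H[((size_t)k * npat + i) * 4];
            const double Ssum = h[0] + h[1] + h[2] + h[3];
            const double b = pdiff * Ssum;
            double* u = UP(cb, k, i);
            u[0] = ee * h[0] + b; u[1] = ee * h[1] + b;
            u[2] = ee * h[2] + b; u[3] = ee * h[3] + b;
            double m = u[0];
            if (u[1] > m) m = u[1];
            if (u[2] > m) m = u[2];
            if (u[3] > m) m = u[3];
            double sc = Hs[(size_t)k * npat + i];
            if (m > 0 && m != 1.0) {
              u[0] /= m; u[1] /= m; u[2] /= m; u[3] /= m;
              sc += std::log(m);
            }
            USC(cb, k, i) = sc;
          }
        }
      }
    }
    const double new_ll = down_pass();
    if (new_ll < ll - 1e-9) {  // stale-partials overshoot: revert and stop
      el = el_before;
      break;
    }
    const double improved = new_ll - ll;
    ll = new_ll;
    if (improved < tol) break;
  }
  #undef DOWN
  #undef DSC
  #undef MSG
  #undef UP
  #undef USC
  return List::create(_["edge_len"] = NumericVector(el.begin(), el.end()),
                      _["loglik"] = ll, _["sweeps"] = sweeps);
}
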