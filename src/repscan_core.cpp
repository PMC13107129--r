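// Compiled kernels for structure superposition, TM-score optimization,
// the heuristic structural alignment search, and profile Needleman-Wunsch.
// All geometry is in Angstroms; correspondences are 1-based on the R side.
#include <RcppArmadillo.h>

#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// d0 scale of the TM-score, floored at 0.5 A (also used for Lnorm < 16,
// where the cube-root formula is undefined/negative).
double tm_d0(int lnorm) {
  if (lnorm < 16) return 0.5;
  double d0 = 1.24 * std::cbrt((double)lnorm - 15.0) - 1.8;
  return (d0 < 0.5) ? 0.5 : d0;
}

struct RigidFit {
  arma::mat33 R;
  arma::vec3 t;
  double rmsd;
};

// Least-squares rigid fit mapping X onto Y (rows are points), reflections
// excluded via the sign correction on the smallest singular vector.
RigidFit kabsch_fit(const arma::mat& X, const arma::mat& Y) {
  arma::rowvec cx = arma::mean(X, 0);
  arma::rowvec cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx;
  arma::mat Yc = Y.each_row() - cy;
  arma::mat H = Xc.t() * Yc;  // 3x3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  RigidFit f;
  f.R = V * D * U.t();
  f.t = arma::vec3(cy.t() - f.R * cx.t());
  arma::mat Xt = (f.R * Xc.t()).t();
  double ss = arma::accu(arma::square(Xt - Yc));
  f.rmsd = std::sqrt(ss / (double)X.n_rows);
  return f;
}

arma::mat apply_fit(const RigidFit& f, const arma::mat& X) {
  arma::mat Xt = (f.R * X.t()).t();
  Xt.each_row() += f.t.t();
  return Xt;
}

double tm_of_dist(const arma::vec& d, double d0, int lnorm) {
  double s = 0.0;
  for (arma::uword i = 0; i < d.n_elem; ++i)
    s += 1.0 / (1.0 + (d(i) / d0) * (d(i) / d0));
  return s / (double)lnorm;
}

// TM-score-style refinement: starting from a subset of the correspondence,
// alternate (superpose on subset) -> (collect pairs within a distance cutoff)
// until the subset is stable; the cutoff is relaxed if fewer than 3 pairs
// survive. Returns the best TM seen together with its superposition.
struct TMResult {
  double tm;
  double rmsd_full;
  RigidFit fit;
};

TMResult tm_refine(const arma::mat& M, const arma::mat& T,
                   const arma::uvec& start, double d0, int lnorm) {
  const arma::uword k = M.n_rows;
  TMResult best;
  best.tm = -1.0;
  arma::uvec sub = start;
  arma::uvec prev;
  for (int it = 0; it < 30; ++it) {
    if (sub.n_elem < 3) break;
    RigidFit f = kabsch_fit(M.rows(sub), T.rows(sub));
    arma::mat Mt = apply_fit(f, M);
    arma::vec d(k);
    for (arma::uword i = 0; i < k; ++i)
      d(i) = arma::norm(Mt.row(i) - T.row(i), 2);
    double tm = tm_of_dist(d, d0, lnorm);
    if (tm > best.tm) {
      best.tm = tm;
      best.fit = f;
      double ss = 0.0;
      for (arma::uword i = 0; i < k; ++i) ss += d(i) * d(i);
      best.rmsd_full = std::sqrt(ss / (double)k);
    }
    double dcut = d0;
    arma::uvec nxt;
    for (int grow = 0; grow < 20; ++grow) {
      nxt = arma::find(d < dcut + 0.5 * grow);
      if (nxt.n_elem >= 3) break;
    }
    if (nxt.n_elem < 3) break;
    if (prev.n_elem == nxt.n_elem && arma::all(prev == nxt)) break;
    prev = sub;
    sub = nxt;
    if (sub.n_elem == prev.n_elem && arma::all(sub == prev)) break;
  }
  return best;
}

// Full TM evaluation of one correspondence: multiple starts, each refined;
// the maximum TM wins (the TM-score convention). Long correspondences use
// contiguous-fragment starts; short ones (k <= 10) can afford every
// 3-subset, which makes the evaluation near-exact at oracle scale.
TMResult tm_eval(const arma::mat& M, const arma::mat& T, double d0, int lnorm) {
  const int k = (int)M.n_rows;
  TMResult best;
  best.tm = -1.0;
  std::vector<int> lens;
  lens.push_back(k);
  if (k >= 8) lens.push_back(k / 2);
  if (k >= 16) lens.push_back(k / 4);
  for (int L : lens) {
    int step = std::max(1, L / 2);
    for (int off = 0; off + L <= k; off += step) {
      arma::uvec sub = arma::regspace<arma::uvec>(off, off + L - 1);
      TMResult r = tm_refine(M, T, sub, d0, lnorm);
      if (r.tm > best.tm) best = r;
    }
  }
  if (k <= 10) {
    arma::uvec sub(3);
    for (int a = 0; a < k - 2; ++a) {
      for (int b = a + 1; b < k - 1; ++b) {
        for (int c = b + 1; c < k; ++c) {
          sub[0] = a;
          sub[1] = b;
          sub[2] = c;
          TMResult r = tm_refine(M, T, sub, d0, lnorm);
          if (r.tm > best.tm) best = r;
        }
      }
    }
  }
  return best;
}

// Needleman-Wunsch with linear gap penalty and free terminal gaps, on a
// precomputed similarity matrix S (na x nb). Tie order: diagonal, then up
// (gap in B), then left. Returns matched index pairs (0-based).
void nw_linear(const arma::mat& S, double gap,
               std::vector<std::pair<int, int>>& out) {
  const int na = S.n_rows, nb = S.n_cols;
  arma::mat F(na + 1, nb + 1, arma::fill::zeros);
  arma::Mat<int> P(na + 1, nb + 1, arma::fill::zeros);  // 1 diag, 2 up, 3 left
  for (int i = 1; i <= na; ++i) P(i, 0) = 2;
  for (int j = 1; j <= nb; ++j) P(0, j) = 3;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double sd = F(i - 1, j - 1) + S(i - 1, j - 1);
      double su = F(i - 1, j) + (j == nb ? 0.0 : gap);
      double sl = F(i, j - 1) + (i == na ? 0.0 : gap);
      if (sd >= su && sd >= sl) {
        F(i, j) = sd;
        P(i, j) = 1;
      } else if (su >= sl) {
        F(i, j) = su;
        P(i, j) = 2;
      } else {
        F(i, j) = sl;
        P(i, j) = 3;
      }
    }
  }
  out.clear();
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (p == 1) {
      out.push_back({i - 1, j - 1});
      --i;
      --j;
    } else if (p == 2) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(out.begin(), out.end());
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& mobile, const arma::mat& target) {
  RigidFit f = kabsch_fit(mobile, target);
  return List::create(_["rotation"] = arma::mat(f.R), _["translation"] = f.t,
                      _["rmsd"] = f.rmsd);
}

//' @noRd
// [[Rcpp::export(name = ".tm_optimize_cpp")]]
List tm_optimize_cpp(const arma::mat& mobile, const arma::mat& target,
                     const arma::imat& corr, int lnorm) {
  const int k = corr.n_rows;
  arma::mat M(k, 3), T(k, 3);
  for (int i = 0; i < k; ++i) {
    M.row(i) = mobile.row(corr(i, 0) - 1);
    T.row(i) = target.row(corr(i, 1) - 1);
  }
  double d0 = tm_d0(lnorm);
  TMResult r = tm_eval(M, T, d0, lnorm);
  return List::create(_["tm"] = r.tm, _["rmsd"] = r.rmsd_full,
                      _["rotation"] = arma::mat(r.fit.R), _["translation"] = r.fit.t,
                      _["d0"] = d0);
}

//' @noRd
// [[Rcpp::export(name = ".align_structures_cpp")]]
List align_structures_cpp(const arma::mat& mobile, const arma::mat& target,
                          int lnorm, double gap, int window, int step,
                          int max_iter) {
  const int la = mobile.n_rows, lb = target.n_rows;
  double d0 = tm_d0(lnorm);

  // --- seed correspondences ---
  std::vector<std::vector<std::pair<int, int>>> seeds;
  // gapless threading at every offset with >= 3 overlapping residues
  for (int off = -(lb - 3); off <= la - 3; ++off) {
    std::vector<std::pair<int, int>> s;
    for (int i = 0; i < la; ++i) {
      int j = i - off;
      if (j >= 0 && j < lb) s.push_back({i, j});
    }
    if ((int)s.size() >= 3) seeds.push_back(std::move(s));
  }
  // fragment pairs: length-`window` windows at stride `step` in both chains;
  // when the chains are shorter than the window the stride degenerates to 1
  // (a stride tuned for protein-scale chains would leave single seeds)
  int w = std::min(window, std::min(la, lb));
  if (w < window) step = 1;
  if (w >= 3) {
    for (int ia = 0; ia + w <= la; ia += step) {
      for (int ib = 0; ib + w <= lb; ib += step) {
        std::vector<std::pair<int, int>> s;
        for (int q = 0; q < w; ++q) s.push_back({ia + q, ib + q});
        seeds.push_back(std::move(s));
      }
    }
  }

  double best_tm = -1.0;
  double best_rmsd = 0.0;
  RigidFit best_fit;
  std::vector<std::pair<int, int>> best_corr;
  typedef std::vector<std::pair<int, int>> Corr;
  // The refinement step (superpose on corr -> NW on the distance scores)
  // is a deterministic map corr -> corr, so its transitions can be cached:
  // seeds that fall onto an already-explored trajectory reuse it, which
  // changes nothing in the result, only the work done.
  std::map<Corr, Corr> trans;
  std::map<Corr, std::pair<double, int>> finals;  // corr -> (tm, id)
  std::vector<TMResult> final_fits;
  const double d0sq = d0 * d0;

  auto refine_once = [&](const Corr& corr) -> Corr {
    auto hit = trans.find(corr);
    if (hit != trans.end()) return hit->second;
    arma::mat M(corr.size(), 3), T(corr.size(), 3);
    for (size_t q = 0; q < corr.size(); ++q) {
      M.row(q) = mobile.row(corr[q].first);
      T.row(q) = target.row(corr[q].second);
    }
    RigidFit f = kabsch_fit(M, T);
    arma::mat Mt = apply_fit(f, mobile);
    arma::mat S(la, lb);
    for (int j = 0; j < lb; ++j) {
      const double tx = target.at(j, 0), ty = target.at(j, 1),
                   tz = target.at(j, 2);
      for (int i = 0; i < la; ++i) {
        const double dx = Mt.at(i, 0) - tx, dy = Mt.at(i, 1) - ty,
                     dz = Mt.at(i, 2) - tz;
        S.at(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d0sq);
      }
    }
    Corr nxt;
    nw_linear(S, gap, nxt);
    trans[corr] = nxt;
    return nxt;
  };

  for (size_t sidx = 0; sidx < seeds.size(); ++sidx) {
    Corr corr = seeds[sidx];
    for (int it = 0; it < max_iter; ++it) {
      if ((int)corr.size() < 3) break;
      Corr nxt = refine_once(corr);
      if (nxt == corr) break;
      corr = std::move(nxt);
    }
    if ((int)corr.size() < 3) continue;
    double tm;
    auto fin = finals.find(corr);
    if (fin != finals.end()) {
      tm = fin->second.first;
    } else {
      arma::mat M(corr.size(), 3), T(corr.size(), 3);
      for (size_t q = 0; q < corr.size(); ++q) {
        M.row(q) = mobile.row(corr[q].first);
        T.row(q) = target.row(corr[q].second);
      }
      TMResult r = tm_eval(M, T, d0, lnorm);
      finals[corr] = {r.tm, (int)final_fits.size()};
      final_fits.push_back(r);
      tm = r.tm;
    }
    if (tm > best_tm + 1e-12) {  // strict improvement: first seed wins ties
      const TMResult& r = final_fits[finals[corr].second];
      best_tm = tm;
      best_rmsd = r.rmsd_full;
      best_fit = r.fit;
      best_corr = corr;
    }
  }

  if (best_corr.empty()) stop("alignment search found no valid correspondence");

  // For tiny chains, finish with local hill-climbing on the TM objective
  // itself (add / drop / move one pair, keeping monotonicity): the gap
  // penalty of the NW stage can refuse a gapped correspondence whose TM
  // gain is smaller than the penalty, which only matters at oracle scale.
  if (la <= 12 && lb <= 12) {
    auto eval_corr = [&](const Corr& c) -> double {
      auto fin = finals.find(c);
      if (fin != finals.end()) return fin->second.first;
      arma::mat M(c.size(), 3), T(c.size(), 3);
      for (size_t q = 0; q < c.size(); ++q) {
        M.row(q) = mobile.row(c[q].first);
        T.row(q) = target.row(c[q].second);
      }
      TMResult r = tm_eval(M, T, d0, lnorm);
      finals[c] = {r.tm, (int)final_fits.size()};
      final_fits.push_back(r);
      return r.tm;
    };
    // climb from every converged basin, not only the best one
    std::vector<Corr> climb_starts;
    climb_starts.push_back(best_corr);
    for (auto& kv : finals) climb_starts.push_back(kv.first);
    // at very small scale every size-3 monotone correspondence is an
    // affordable start, which makes the search exhaustive in practice
    if (la <= 8 && lb <= 8) {
      for (int i1 = 0; i1 < la - 2; ++i1)
        for (int i2 = i1 + 1; i2 < la - 1; ++i2)
          for (int i3 = i2 + 1; i3 < la; ++i3)
            for (int j1 = 0; j1 < lb - 2; ++j1)
              for (int j2 = j1 + 1; j2 < lb - 1; ++j2)
                for (int j3 = j2 + 1; j3 < lb; ++j3)
                  climb_starts.push_back(
                      Corr{{i1, j1}, {i2, j2}, {i3, j3}});
    }
    for (size_t cs = 0; cs < climb_starts.size(); ++cs) {
    Corr cur = climb_starts[cs];
    double cur_tm = eval_corr(cur);
    bool improved = true;
    int guard = 0;
    while (improved && ++guard < 200) {
      improved = false;
      std::vector<Corr> neigh;
      const Corr& c = cur;
      const int kc = (int)c.size();
      for (int q = 0; q < kc; ++q) {
        if (kc > 3) {  // drop one pair
          Corr v = c;
          v.erase(v.begin() + q);
          neigh.push_back(v);
        }
        // move one pair within its monotone slot
        int ilo = (q == 0) ? 0 : c[q - 1].first + 1;
        int ihi = (q == kc - 1) ? la - 1 : c[q + 1].first - 1;
        int jlo = (q == 0) ? 0 : c[q - 1].second + 1;
        int jhi = (q == kc - 1) ? lb - 1 : c[q + 1].second - 1;
        for (int i = ilo; i <= ihi; ++i) {
          for (int j = jlo; j <= jhi; ++j) {
            if (i == c[q].first && j == c[q].second) continue;
            Corr v = c;
            v[q] = {i, j};
            neigh.push_back(v);
          }
        }
      }
      // add one pair in any monotone slot
      for (int q = 0; q <= kc; ++q) {
        int ilo = (q == 0) ? 0 : c[q - 1].first + 1;
        int ihi = (q == kc) ? la - 1 : c[q].first - 1;
        int jlo = (q == 0) ? 0 : c[q - 1].second + 1;
        int jhi = (q == kc) ? lb - 1 : c[q].second - 1;
        for (int i = ilo; i <= ihi; ++i) {
          for (int j = jlo; j <= jhi; ++j) {
            Corr v = c;
            v.insert(v.begin() + q, {i, j});
            neigh.push_back(v);
          }
        }
      }
      for (const Corr& v : neigh) {
        double tm = eval_corr(v);
        if (tm > cur_tm + 1e-12) {
          cur_tm = tm;
          cur = v;
          improved = true;
        }
        if (tm > best_tm + 1e-12) {
          best_tm = tm;
          best_corr = v;
          const TMResult& r = final_fits[finals[v].second];
          best_rmsd = r.rmsd_full;
          best_fit = r.fit;
        }
      }
    }
    }
  }
  arma::imat C(best_corr.size(), 2);
  for (size_t q = 0; q < best_corr.size(); ++q) {
    C(q, 0) = best_corr[q].first + 1;
    C(q, 1) = best_corr[q].second + 1;
  }
  return List::create(_["tm"] = best_tm, _["rmsd"] = best_rmsd,
                      _["correspondence"] = C, _["rotation"] = arma::mat(best_fit.R),
                      _["translation"] = best_fit.t, _["d0"] = d0);
}

//' @noRd
// [[Rcpp::export(name = ".nw_profile_cpp")]]
IntegerVector nw_profile_cpp(const arma::mat& A, const arma::mat& B,
                             double gap_open, double gap_ext) {
  // A, B: state-frequency profiles (n_states x n_cols); column score is the
  // expected identity sum_s A[s,i]*B[s,j]. Affine gaps, costs positive.
  const int na = A.n_cols, nb = B.n_cols;
  const double NEG = -1e30;
  arma::mat Mm(na + 1, nb + 1), Ix(na + 1, nb + 1), Iy(na + 1, nb + 1);
  arma::Mat<int> Pm(na + 1, nb + 1), Px(na + 1, nb + 1), Py(na + 1, nb + 1);
  Mm.fill(NEG);
  Ix.fill(NEG);
  Iy.fill(NEG);
  Mm(0, 0) = 0.0;
  for (int i = 1; i <= na; ++i) {
    Ix(i, 0) = -gap_open - gap_ext * (i - 1);
    Px(i, 0) = (i == 1) ? 1 : 2;  // 1: from M, 2: from Ix
  }
  for (int j = 1; j <= nb; ++j) {
    Iy(0, j) = -gap_open - gap_ext * (j - 1);
    Py(0, j) = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double sc = arma::dot(A.col(i - 1), B.col(j - 1));
      // M state: tie order M, Ix, Iy
      double m1 = Mm(i - 1, j - 1), m2 = Ix(i - 1, j - 1), m3 = Iy(i - 1, j - 1);
      if (m1 >= m2 && m1 >= m3) {
        Mm(i, j) = m1 + sc;
        Pm(i, j) = 1;
      } else if (m2 >= m3) {
        Mm(i, j) = m2 + sc;
        Pm(i, j) = 2;
      } else {
        Mm(i, j) = m3 + sc;
        Pm(i, j) = 3;
      }
      // Ix: consume A column (gap in B)
      double x1 = Mm(i - 1, j) - gap_open, x2 = Ix(i - 1, j) - gap_ext;
      if (x1 >= x2) {
        Ix(i, j) = x1;
        Px(i, j) = 1;
      } else {
        Ix(i, j) = x2;
        Px(i, j) = 2;
      }
      // Iy: consume B column (gap in A)
      double y1 = Mm(i, j - 1) - gap_open, y2 = Iy(i, j - 1) - gap_ext;
      if (y1 >= y2) {
        Iy(i, j) = y1;
        Py(i, j) = 1;
      } else {
        Iy(i, j) = y2;
        Py(i, j) = 2;
      }
    }
  }
  // traceback from the best terminal state; tie order M, Ix, Iy
  int state;  // 0 M, 1 Ix, 2 Iy
  double e0 = Mm(na, nb), e1 = Ix(na, nb), e2 = Iy(na, nb);
  if (e0 >= e1 && e0 >= e2)
    state = 0;
  else if (e1 >= e2)
    state = 1;
  else
    state = 2;
  std::vector<int> moves;  // 0 diag, 1 A-gap-in-B (up), 2 B-gap-in-A (left)
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    if (i == 0)
      state = 2;
    else if (j == 0)
      state = 1;
    if (state == 0) {
      int p = Pm(i, j);
      moves.push_back(0);
      --i;
      --j;
      state = (p == 1) ? 0 : (p == 2 ? 1 : 2);
    } else if (state == 1) {
      int p = Px(i, j);
      moves.push_back(1);
      --i;
      state = (p == 1) ? 0 : 1;
    } else {
      int p = Py(i, j);
      moves.push_back(2);
      --j;
      state = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
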