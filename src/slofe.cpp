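#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, U/T=3, anything else (N) = -1.
static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

// Pair codes follow the ViennaRNA convention used by the parameter tables:
// 0 = no pair, 1 = CG, 2 = GC, 3 = GU, 4 = UG, 5 = AU, 6 = UA.
static inline int pair_code(int a, int b, bool allow_gu) {
  if (a < 0 || b < 0) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  if (allow_gu) {
    if (a == 2 && b == 3) return 3;
    if (a == 3 && b == 2) return 4;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Motif scanner.
//
// One candidate per (loop_start, loop_len): the stem is extended symmetrically
// outwards from the loop while the mismatch budget holds, then trimmed so the
// outermost position is a genuine pair. The loop-adjacent (innermost) position
// must pair, otherwise the same locus is a candidate at a larger loop size.
// Candidates containing N are discarded. Returns 1-based [start, end, stem].
// [[Rcpp::export(name = ".scan_candidates_cpp")]]
IntegerMatrix scan_candidates_cpp(std::string seq, int stem_min, int stem_max,
                                  int loop_min, int loop_max, bool allow_gu,
                                  int max_mismatch) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  std::vector<int> starts, ends, stems;

  for (int a = 1; a + loop_min <= n - 1; ++a) { // a = loop start (0-based)
    for (int l = loop_min; l <= loop_max; ++l) {
      int b = a + l - 1;          // loop end
      if (b >= n - 1) break;
      bool bad_loop = false;
      for (int k = a; k <= b; ++k) if (s[k] < 0) { bad_loop = true; break; }
      if (bad_loop) continue;
      // innermost stem position must pair
      if (pair_code(s[a - 1], s[b + 1], allow_gu) == 0) continue;
      int mism = 0, slen = 0, last_paired = 0;
      for (int k = 1; k <= stem_max; ++k) {
        int i = a - k, j = b + k;
        if (i < 0 || j >= n) break;
        if (s[i] < 0 || s[j] < 0) break;
        if (pair_code(s[i], s[j], allow_gu) != 0) {
          last_paired = k;
          slen = k;
        } else {
          if (++mism > max_mismatch) { slen = last_paired; break; }
          slen = k;
        }
      }
      int keep = std::min(slen, last_paired); // trim outer mismatches
      if (keep >= stem_min) {
        starts.push_back(a - keep + 1); // 1-based
        ends.push_back(b + keep + 1);
        stems.push_back(keep);
      }
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
    out(i, 2) = stems[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "stem_len");
  return out;
}

// ---------------------------------------------------------------------------
// Single-hairpin MFE folder.
//
// Nearest-neighbor model over one helix closed by a hairpin loop: stacking,
// bulge and interior loops (combined unpaired span capped), hairpin-loop
// initiation with terminal mismatch, terminal-AU/GU penalties at the helix
// ends, NINIO asymmetry. No multibranch structures. Energies in kcal/mol.
//
// Parameter pack (all kcal/mol):
//  stack:    6x6 matrix [pair(i,j)][pair(i+1,j-1)]
//  hp_init:  length-31 vector, hairpin init for loop sizes 1..31 (Inf below 3)
//  hp_mm:    6x4x4 flattened [pair][a][b], terminal mismatch of hairpin loop
//  bulge:    length-31 vector
//  interior: length-31 vector
//  ninio_m / ninio_max: asymmetry slope and cap
//  term_au:  penalty for AU/GU helix end
//  lxc:      log extrapolation coefficient for long loops
struct EPar {
  NumericMatrix stack;
  NumericVector hp_init, hp_mm, bulge, interior;
  double ninio_m, ninio_max, term_au, lxc;
  int max_intloop;
};

static inline double loop_init(const NumericVector& tab, int size, double lxc) {
  if (size <= 0) return R_PosInf;
  if (size <= tab.size()) return tab[size - 1];
  int mx = tab.size();
  return tab[mx - 1] + lxc * std::log((double) size / mx);
}

// pair code of the same pair read 3'->5' (CG<->GC, GU<->UG, AU<->UA)
static inline int rtype(int pc) {
  static const int r[7] = {0, 2, 1, 4, 3, 6, 5};
  return r[pc];
}

static inline double hp_mismatch(const EPar& p, int pc, int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  return p.hp_mm[(pc - 1) * 16 + a * 4 + b];
}

static inline double end_penalty(const EPar& p, int pc) {
  return (pc >= 3) ? p.term_au : 0.0; // GU, UG, AU, UA ends
}

// [[Rcpp::export(name = ".fold_hairpin_cpp")]]
List fold_hairpin_cpp(std::string seq, List pars, int min_loop, bool allow_gu) {
  int n = (int) seq.size();
  EPar p;
  p.stack = as<NumericMatrix>(pars["stack"]);
  p.hp_init = as<NumericVector>(pars["hp_init"]);
  p.hp_mm = as<NumericVector>(pars["hp_mm"]);
  p.bulge = as<NumericVector>(pars["bulge"]);
  p.interior = as<NumericVector>(pars["interior"]);
  p.ninio_m = as<double>(pars["ninio_m"]);
  p.ninio_max = as<double>(pars["ninio_max"]);
  p.term_au = as<double>(pars["term_au"]);
  p.lxc = as<double>(pars["lxc"]);
  p.max_intloop = as<int>(pars["max_intloop"]);

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);

  std::string structure(n, '.');
  if (n < min_loop + 2)
    return List::create(_["structure"] = structure, _["dG"] = 0.0);

  // V[i][j]: best energy of a hairpin closed by pair (i,j); traceback stores
  // the inner pair (or -1 for hairpin-loop closure).
  std::vector< std::vector<double> > V(n, std::vector<double>(n, R_PosInf));
  std::vector< std::vector<int> > TI(n, std::vector<int>(n, -2));
  std::vector< std::vector<int> > TJ(n, std::vector<int>(n, -2));

  for (int d = min_loop + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pc = pair_code(s[i], s[j], allow_gu);
      if (pc == 0) continue;
      // hairpin-loop closure
      int ls = j - i - 1;
      double best = loop_init(p.hp_init, ls, p.lxc);
      if (R_finite(best)) {
        // triloops take the helix-end penalty; larger loops a terminal mismatch
        if (ls == 3) best += end_penalty(p, pc);
        else best += hp_mismatch(p, pc, s[i + 1], s[j - 1]);
      }
      int bi = -1, bj = -1;
      // stack / bulge / interior to inner pair (k, l)
      for (int k1 = 0; k1 <= p.max_intloop; ++k1) {
        int k = i + 1 + k1;
        if (k >= j - min_loop - 1) break;
        for (int k2 = 0; k2 <= p.max_intloop - k1; ++k2) {
          int l = j - 1 - k2;
          if (l - k < min_loop + 1) break;
          int pc2 = pair_code(s[k], s[l], allow_gu);
          if (pc2 == 0) continue;
          if (!R_finite(V[k][l])) continue;
          double e;
          if (k1 == 0 && k2 == 0) {
            e = p.stack(pc - 1, rtype(pc2) - 1);
          } else if (k1 == 0 || k2 == 0) {
            int bs = k1 + k2;
            e = loop_init(p.bulge, bs, p.lxc);
            if (bs == 1) {
              e += p.stack(pc - 1, rtype(pc2) - 1); // size-1 bulge keeps the stack
            } else {
              e += end_penalty(p, pc) + end_penalty(p, pc2);
            }
          } else {
            e = loop_init(p.interior, k1 + k2, p.lxc)
              + std::min(p.ninio_max, p.ninio_m * std::abs(k1 - k2))
              + end_penalty(p, pc) + end_penalty(p, pc2);
          }
          e += V[k][l];
          if (e < best) { best = e; bi = k; bj = l; }
        }
      }
      V[i][j] = best;
      TI[i][j] = bi;
      TJ[i][j] = bj;
    }
  }

  // closed structure energy includes the outer helix-end penalty
  double mfe = 0.0;
  int oi = -1, oj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      if (!R_finite(V[i][j])) continue;
      int pc = pair_code(s[i], s[j], allow_gu);
      double e = V[i][j] + end_penalty(p, pc);
      if (e < mfe) { mfe = e; oi = i; oj = j; }
    }
  }
  if (oi < 0)
    return List::create(_["structure"] = structure, _["dG"] = 0.0);

  int i = oi, j = oj;
  while (i >= 0) {
    structure[i] = '(';
    structure[j] = ')';
    int ni = TI[i][j], nj = TJ[i][j];
    i = ni; j = nj;
  }
  return List::create(_["structure"] = structure, _["dG"] = mfe);
}
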