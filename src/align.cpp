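#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <climits>

using namespace Rcpp;

// Affine-gap pairwise alignment (local Smith-Waterman or global
// Needleman-Wunsch) over {A,C,G,T,N}. 'N' never matches anything,
// including another 'N' (conservative identity).
//
// Scoring convention: a gap of length L contributes
//   gap_open + L * gap_extend   (both parameters <= 0).
//
// Traceback is stored as one byte per cell:
//   bits 0-1 : predecessor state of M (0 = alignment start, 1 = M,
//              2 = X, 3 = Y)
//   bit 2    : X entered from M (gap open) rather than X (extend)
//   bit 3    : Y entered from M (gap open) rather than Y (extend)
// Ties prefer M over X over Y, and gap extension over re-opening, so
// the traced alignment is deterministic. The best local cell is the
// first maximum in row-major order (smallest query end, then target
// end), which for tandem identical hits selects the leftmost copy.

static const int NEG_INF = INT_MIN / 4;

// IUPAC base-set bitmasks (A=1, C=2, G=4, T=8); 0 for invalid characters.
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
  case 'K': return 12; case 'M': return 3; case 'B': return 14; case 'D': return 13;
  case 'H': return 11; case 'V': return 7; case 'N': return 15;
  default: return 0;
  }
}

// Two modes. Strict (default): only identical plain bases match; ambiguity
// codes, N included, never match anything. IUPAC-aware (used for
// consensus-involved comparisons): codes match when their base sets
// intersect, except N, which still matches nothing (it marks masked or
// unknown sequence, not a permissive consensus call).
static inline int subst_score(char a, char b, int match, int mismatch,
                              bool iupac) {
  if (a == 'N' || b == 'N') return mismatch;
  if (iupac) {
    return (iupac_mask(a) & iupac_mask(b)) ? match : mismatch;
  }
  if (a != b) return mismatch;
  switch (a) {
  case 'A': case 'C': case 'G': case 'T': return match;
  default: return mismatch;
  }
}

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string q, std::string t,
                      int match, int mismatch,
                      int gap_open, int gap_extend,
                      std::string type, bool iupac) {
  const int n = (int) q.size();
  const int m = (int) t.size();
  const bool local = (type == "local");
  const int go = gap_open + gap_extend; // cost of the first gapped base
  const int ge = gap_extend;

  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<int> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  // row 0
  Mprev[0] = 0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = local ? 0 : NEG_INF;
    Xprev[j] = NEG_INF;
    if (local) {
      Yprev[j] = NEG_INF;
    } else {
      Yprev[j] = go + (j - 1) * ge;
      tb[j] = (j == 1) ? 8 : 0; // Y from M at j=1, else Y-extend
    }
  }

  int best = 0, best_i = 0, best_j = 0; // local tracking
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t) i * (m + 1);
    Mcur[0] = local ? 0 : NEG_INF;
    Ycur[0] = NEG_INF;
    if (local) {
      Xcur[0] = NEG_INF;
    } else {
      Xcur[0] = go + (i - 1) * ge;
      tb[row] = (i == 1) ? 4 : 0; // X from M at i=1, else X-extend
    }
    for (int j = 1; j <= m; ++j) {
      uint8_t code = 0;
      // M: consume q[i-1] and t[j-1]
      int s = subst_score(q[i - 1], t[j - 1], match, mismatch, iupac);
      int diag = Mprev[j - 1];
      uint8_t msrc = 1;
      if (Xprev[j - 1] > diag) { diag = Xprev[j - 1]; msrc = 2; }
      if (Yprev[j - 1] > diag) { diag = Yprev[j - 1]; msrc = 3; }
      if (local && diag < 0) { diag = 0; msrc = 0; }
      int Mv = (diag <= NEG_INF) ? NEG_INF : diag + s;
      code |= msrc;
      // X: gap in target (consume query char)
      int x_open = (Mprev[j] <= NEG_INF) ? NEG_INF : Mprev[j] + go;
      int x_ext  = (Xprev[j] <= NEG_INF) ? NEG_INF : Xprev[j] + ge;
      int Xv;
      if (x_open > x_ext) { Xv = x_open; code |= 4; } else { Xv = x_ext; }
      // Y: gap in query (consume target char)
      int y_open = (Mcur[j - 1] <= NEG_INF) ? NEG_INF : Mcur[j - 1] + go;
      int y_ext  = (Ycur[j - 1] <= NEG_INF) ? NEG_INF : Ycur[j - 1] + ge;
      int Yv;
      if (y_open > y_ext) { Yv = y_open; code |= 8; } else { Yv = y_ext; }

      Mcur[j] = Mv; Xcur[j] = Xv; Ycur[j] = Yv;
      tb[row + j] = code;
      if (local && Mv > best) { best = Mv; best_i = i; best_j = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int score, ei, ej, state; // state: 1=M, 2=X, 3=Y
  if (local) {
    if (best <= 0) {
      return List::create(_["score"] = 0,
                          _["q_start"] = 0, _["q_end"] = 0,
                          _["t_start"] = 0, _["t_end"] = 0,
                          _["aligned_q"] = "", _["aligned_t"] = "");
    }
    score = best; ei = best_i; ej = best_j; state = 1;
  } else {
    // after the loop Mprev holds row n
    score = Mprev[m]; state = 1;
    if (Xprev[m] > score) { score = Xprev[m]; state = 2; }
    if (Yprev[m] > score) { score = Yprev[m]; state = 3; }
    ei = n; ej = m;
  }

  std::string aq, at;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t) i * (m + 1) + j];
    if (state == 1) {
      if (i == 0 || j == 0) break; // global boundary handled by X/Y states
      uint8_t msrc = code & 3;
      aq.push_back(q[i - 1]); at.push_back(t[j - 1]);
      --i; --j;
      if (msrc == 0) { state = 0; break; } // local start
      state = msrc;
    } else if (state == 2) {
      aq.push_back(q[i - 1]); at.push_back('-');
      bool from_m = (code & 4) != 0;
      --i;
      state = from_m ? 1 : 2;
    } else { // state == 3
      aq.push_back('-'); at.push_back(t[j - 1]);
      bool from_m = (code & 8) != 0;
      --j;
      state = from_m ? 1 : 3;
    }
    if (local && state == 0) break;
    if (!local && i == 0 && j == 0) break;
    if (!local && i == 0 && state == 1) state = 3; // forced top row
    if (!local && j == 0 && state == 1) state = 2; // forced left column
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());

  int q_start, t_start;
  if (local) {
    q_start = i + 1; t_start = j + 1;
  } else {
    q_start = n > 0 ? 1 : 0; t_start = m > 0 ? 1 : 0;
    ei = n; ej = m;
  }
  return List::create(_["score"] = score,
                      _["q_start"] = q_start, _["q_end"] = ei,
                      _["t_start"] = t_start, _["t_end"] = ej,
                      _["aligned_q"] = aq, _["aligned_t"] = at);
}
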