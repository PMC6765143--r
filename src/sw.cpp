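// Affine-gap Smith-Waterman local alignment (Gotoh), BLASTN-style scoring:
// a gap of length k costs gap_open + k * gap_extend.  Plus-strand only; the
// R wrapper handles the reverse complement of the subject.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

struct Params {
  int match, mismatch, gap_open, gap_extend;
};

inline int subst(char a, char b, const Params& p) {
  // N never matches anything, including itself
  if (a == 'N' || b == 'N') return p.mismatch;
  return (a == b) ? p.match : p.mismatch;
}

const int NEG = -(1 << 28);

// score-only pass, O(m) memory
int sw_score_one(const std::string& a, const std::string& b, const Params& p) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  const int go = p.gap_open + p.gap_extend, ge = p.gap_extend;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;      // H[i-1][j-1]
    int Fj = NEG;      // F for current row (gap in b, vertical)
    int Hprev = 0;     // H[i][j-1]
    H[0] = 0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - go, E[j] - ge);          // uses row i-1 values
      Fj = std::max(Hprev - go, Fj - ge);
      int h = diag + subst(a[i - 1], b[j - 1], p);
      if (E[j] > h) h = E[j];
      if (Fj > h) h = Fj;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export(name = ".sw_score_many")]]
IntegerVector sw_score_many(CharacterVector a, CharacterVector b,
                            int match, int mismatch, int gap_open, int gap_extend) {
  if (a.size() != b.size()) stop("a and b must have the same length");
  Params p{match, mismatch, gap_open, gap_extend};
  IntegerVector out(a.size());
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    out[k] = sw_score_one(std::string(a[k]), std::string(b[k]), p);
  }
  return out;
}

// Full alignment with traceback.  Tie-breaking in H: diagonal > up > left.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  Params p{match, mismatch, gap_open, gap_extend};
  const int go = gap_open + gap_extend, ge = gap_extend;
  if ((double)(n + 1) * (double)(m + 1) > 6.4e7)
    stop("sequences too long for alignment traceback");

  // E: gap in query a (consumes b_j, "left"); F: gap in subject b ("up")
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // tbH: 0 stop, 1 diag, 2 up(F), 3 left(E); tbE/tbF: 1 open (from H), 0 extend
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j, left = idx - 1,
                diagIdx = up - 1;
      int e_open = H[left] - go, e_ext = E[left] - ge;
      E[idx] = std::max(e_open, e_ext);
      tbE[idx] = (e_open >= e_ext) ? 1 : 0;
      int f_open = H[up] - go, f_ext = F[up] - ge;
      F[idx] = std::max(f_open, f_ext);
      tbF[idx] = (f_open >= f_ext) ? 1 : 0;
      int d = H[diagIdx] + subst(a[i - 1], b[j - 1], p);
      int h = d; unsigned char dir = 1;            // diagonal preferred
      if (F[idx] > h) { h = F[idx]; dir = 2; }     // then up
      if (E[idx] > h) { h = E[idx]; dir = 3; }     // then left
      if (h <= 0) { h = 0; dir = 0; }
      H[idx] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["columns"] = 0,
                        _["matches"] = 0, _["q_aln"] = "", _["s_aln"] = "");
  }

  std::string qa, sa;
  int i = bi, j = bj, matches = 0;
  char state = 'H';
  while (true) {
    const int idx = i * (m + 1) + j;
    if (state == 'H') {
      unsigned char dir = tbH[idx];
      if (dir == 0) break;
      if (dir == 1) {
        qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
        --i; --j;
      } else if (dir == 2) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {          // gap in subject, consume a_i
      qa.push_back(a[i - 1]); sa.push_back('-');
      unsigned char open = tbF[idx];
      --i;
      state = open ? 'H' : 'F';
    } else {                            // gap in query, consume b_j
      qa.push_back('-'); sa.push_back(b[j - 1]);
      unsigned char open = tbE[idx];
      --j;
      state = open ? 'H' : 'E';
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["columns"] = (int)qa.size(), _["matches"] = matches,
                      _["q_aln"] = qa, _["s_aln"] = sa);
}
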