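// Affine-gap pairwise alignment (Gotoh three-state DP) with deterministic
// traceback. Gap of length L scores gap_open + (L-1)*gap_extend.
// Tie-break priority everywhere: diagonal (M) > up/gap-in-target (X) >
// left/gap-in-reference (Y); for the local end cell, lowest (i, j) wins.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static const double NEG_INF = -1e18;

// state codes used in traceback matrices
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_START = 3 };

static void build_code(const NumericMatrix& sub, int* code) {
  for (int k = 0; k < 256; ++k) code[k] = -1;
  CharacterVector rn = rownames(sub);
  for (int k = 0; k < rn.size(); ++k) {
    const char* s = CHAR(STRING_ELT(rn, k));
    code[(unsigned char)s[0]] = k;
  }
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, NumericMatrix sub,
                 double open, double ext, bool local) {
  int n = a.size(), m = b.size();
  int code[256];
  build_code(sub, code);
  std::vector<int> ai(n), bj(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = code[(unsigned char)a[i]];
    if (ai[i] < 0) stop("invalid residue '%c' at position %d of first sequence",
                        a[i], i + 1);
  }
  for (int j = 0; j < m; ++j) {
    bj[j] = code[(unsigned char)b[j]];
    if (bj[j] < 0) stop("invalid residue '%c' at position %d of second sequence",
                        b[j], j + 1);
  }

  size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tM((n + 1) * W, FROM_START),
      tX((n + 1) * W, FROM_START), tY((n + 1) * W, FROM_START);
#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[IDX(i, 0)] = open + (i - 1) * ext;
      tX[IDX(i, 0)] = (i == 1) ? FROM_M : FROM_X;
    }
    for (int j = 1; j <= m; ++j) {
      Y[IDX(0, j)] = open + (j - 1) * ext;
      tY[IDX(0, j)] = (j == 1) ? FROM_M : FROM_Y;
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bj[j - 1]);
      // M: priority M > X > Y (> fresh start, local only)
      double vm = M[IDX(i - 1, j - 1)], vx = X[IDX(i - 1, j - 1)],
             vy = Y[IDX(i - 1, j - 1)];
      double bestp = vm;
      unsigned char from = FROM_M;
      if (vx > bestp) { bestp = vx; from = FROM_X; }
      if (vy > bestp) { bestp = vy; from = FROM_Y; }
      if (local && 0.0 > bestp) { bestp = 0.0; from = FROM_START; }
      if (bestp <= NEG_INF / 2) {
        M[IDX(i, j)] = NEG_INF;
      } else {
        M[IDX(i, j)] = bestp + s;
        tM[IDX(i, j)] = from;
      }
      // X: gap in target (consume a[i-1])
      double gm = M[IDX(i - 1, j)] + open, gx = X[IDX(i - 1, j)] + ext,
             gy = Y[IDX(i - 1, j)] + open;
      double bx = gm; unsigned char fx = FROM_M;
      if (gx > bx) { bx = gx; fx = FROM_X; }
      if (gy > bx) { bx = gy; fx = FROM_Y; }
      X[IDX(i, j)] = bx; tX[IDX(i, j)] = fx;
      // Y: gap in reference (consume b[j-1])
      double hm = M[IDX(i, j - 1)] + open, hx = X[IDX(i, j - 1)] + open,
             hy = Y[IDX(i, j - 1)] + ext;
      double by = hm; unsigned char fy = FROM_M;
      if (hx > by) { by = hx; fy = FROM_X; }
      if (hy > by) { by = hy; fy = FROM_Y; }
      Y[IDX(i, j)] = by; tY[IDX(i, j)] = fy;
      if (local && M[IDX(i, j)] > best) {
        best = M[IDX(i, j)]; best_i = i; best_j = j;
      }
    }
  }

  std::string out_a, out_b;
  int i, j, state;
  double score;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  if (local) {
    score = best;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0, _["aligned_a"] = "",
                          _["aligned_b"] = "", _["a_start"] = NA_INTEGER,
                          _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                          _["b_end"] = NA_INTEGER);
    }
    i = best_i; j = best_j; state = FROM_M;
    a_end = i; b_end = j;
  } else {
    double sm = M[IDX(n, m)], sx = X[IDX(n, m)], sy = Y[IDX(n, m)];
    score = sm; state = FROM_M;
    if (sx > score) { score = sx; state = FROM_X; }
    if (sy > score) { score = sy; state = FROM_Y; }
    i = n; j = m;
    a_end = n; b_end = m;
  }

  while (true) {
    unsigned char from;
    if (state == FROM_M) {
      if (i == 0 || j == 0) break;  // global origin (0,0); border safety
      if (local && tM[IDX(i, j)] == FROM_START) {
        // local start cell: consume the match then stop
        out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
        a_start = i; b_start = j;
        break;
      }
      from = tM[IDX(i, j)];
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      a_start = i; b_start = j;  // last consumed match marks a local start
      --i; --j;
    } else if (state == FROM_X) {
      from = tX[IDX(i, j)];
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      --i;
    } else {
      from = tY[IDX(i, j)];
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      --j;
    }
    if (i == 0 && j == 0 && !local) break;
    state = from;
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  if (!local) { a_start = n > 0 ? 1 : 0; b_start = m > 0 ? 1 : 0; }

  return List::create(_["score"] = score, _["aligned_a"] = out_a,
                      _["aligned_b"] = out_b, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
#undef IDX
}
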