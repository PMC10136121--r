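// Exhaustive enumeration oracle for affine-gap alignment scores. Independent
// of the DP in align.cpp: recursively enumerates every alignment path and
// keeps the maximum score. Intended for tiny sequences (length <= 8) only.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Ctx {
  const std::string* a;
  const std::string* b;
  const NumericMatrix* sub;
  double open, ext;
  int code[256];
  double best;
  bool local;
};

double subscore(const Ctx& c, int i, int j) {
  int ca = c.code[(unsigned char)(*c.a)[i]];
  int cb = c.code[(unsigned char)(*c.b)[j]];
  return (*c.sub)(ca, cb);
}

// state: 0 none/match, 1 gap-in-b (consuming a), 2 gap-in-a (consuming b)
void rec(Ctx& c, int i, int j, int state, double score) {
  int n = c.a->size(), m = c.b->size();
  if (c.local) {
    if (score > c.best) c.best = score;
  } else if (i == n && j == m) {
    if (score > c.best) c.best = score;
    return;
  }
  if (i < n && j < m) rec(c, i + 1, j + 1, 0, score + subscore(c, i, j));
  if (i < n) rec(c, i + 1, j, 1, score + (state == 1 ? c.ext : c.open));
  if (j < m) rec(c, i, j + 1, 2, score + (state == 2 ? c.ext : c.open));
}

}  // namespace

// [[Rcpp::export(name = ".brute_best_score")]]
double brute_best_score(std::string a, std::string b, NumericMatrix sub,
                        double open, double ext, bool local) {
  Ctx c;
  c.a = &a; c.b = &b; c.sub = &sub; c.open = open; c.ext = ext;
  c.local = local;
  for (int k = 0; k < 256; ++k) c.code[k] = -1;
  CharacterVector rn = rownames(sub);
  for (int k = 0; k < rn.size(); ++k)
    c.code[(unsigned char)CHAR(STRING_ELT(rn, k))[0]] = k;
  int n = a.size(), m = b.size();
  if (n > 10 || m > 10) stop("brute-force oracle limited to length <= 10");
  if (c.local) {
    c.best = 0.0;
    // every cell is a legal start; empty alignment scores 0
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j) rec(c, i, j, 0, 0.0);
  } else {
    c.best = -1e18;
    rec(c, 0, 0, 0, 0.0);
  }
  return c.best;
}
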