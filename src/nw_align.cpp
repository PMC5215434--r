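#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. A gap of length L costs open + L * extend (first gapped column
// pays open + extend). Traceback ties are broken by preferring the match
// state, then a gap in sequence b ("up"), then a gap in sequence a ("left"),
// so the alignment is deterministic.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  NumericMatrix score, std::string alphabet,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");

  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = i;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("illegal character '%s' in first sequence",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("illegal character '%s' in second sequence",
                        std::string(1, b[j]));
  }

  const double go = gap_open + gap_extend;  // cost of the first gap column
  const size_t W = m + 1;
  // M: a[i] aligned to b[j]; X: gap in b (consume a, "up"); Y: gap in a.
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + gap_extend * i);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + gap_extend * j);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + score(ai[i - 1], bi[j - 1]);
      best = M[u] - go;
      if (X[u] - gap_extend > best) best = X[u] - gap_extend;
      if (Y[u] - go > best) best = Y[u] - go;
      X[c] = best;
      best = M[l] - go;
      if (X[l] - go > best) best = X[l] - go;
      if (Y[l] - gap_extend > best) best = Y[l] - gap_extend;
      Y[c] = best;
    }
  }

  const size_t end = n * W + m;
  int state = 0;  // 0 = M, 1 = X, 2 = Y, priority M > X > Y
  double sc = M[end];
  if (X[end] > sc) { sc = X[end]; state = 1; }
  if (Y[end] > sc) { sc = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); rb.push_back(b[--j]); continue; }
    if (j == 0) { ra.push_back(a[--i]); rb.push_back('-'); continue; }
    const size_t d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                 l = i * W + (j - 1);
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (M[d] >= X[d] && M[d] >= Y[d]) state = 0;
      else if (X[d] >= Y[d]) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      const double mu = M[u] - go, xu = X[u] - gap_extend, yu = Y[u] - go;
      if (mu >= xu && mu >= yu) state = 0;
      else if (xu >= yu) state = 1;
      else state = 2;
      --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const double ml = M[l] - go, xl = X[l] - go, yl = Y[l] - gap_extend;
      if (ml >= xl && ml >= yl) state = 0;
      else if (xl >= yl) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = sc);
}
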