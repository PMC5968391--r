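#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gap penalties.
// A gap of length L costs gap_open + L * gap_extend; terminal gaps are
// penalized like internal ones. Sequences arrive 1-based integer encoded
// (codes index into the substitution matrix). Traceback is deterministic:
// diagonal (match state) preferred over up (gap in b, consumes a) over
// left (gap in a, consumes b), both when choosing the final state and at
// every interior cell.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // state matrices: M diagonal, X gap in b (vertical), Y gap in a (horizontal)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which predecessor state fed each cell (0=M,1=X,2=Y)
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + i * gap_extend);
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * gap_extend);
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: consume both residues; predecessor preference M > X > Y
      {
        double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
        int st = 0; double best = vm;
        if (vx > best) { best = vx; st = 1; }
        if (vy > best) { best = vy; st = 2; }
        M(i, j) = best + s; tbM(i, j) = st;
      }
      // X: gap in b, consume a_i
      {
        double open_from_m = M(i - 1, j) - (gap_open + gap_extend);
        double open_from_y = Y(i - 1, j) - (gap_open + gap_extend);
        double ext = X(i - 1, j) - gap_extend;
        int st = 0; double best = open_from_m;
        if (ext > best) { best = ext; st = 1; }
        if (open_from_y > best) { best = open_from_y; st = 2; }
        X(i, j) = best; tbX(i, j) = st;
      }
      // Y: gap in a, consume b_j
      {
        double open_from_m = M(i, j - 1) - (gap_open + gap_extend);
        double open_from_x = X(i, j - 1) - (gap_open + gap_extend);
        double ext = Y(i, j - 1) - gap_extend;
        int st = 0; double best = open_from_m;
        if (open_from_x > best) { best = open_from_x; st = 1; }
        if (ext > best) { best = ext; st = 2; }
        Y(i, j) = best; tbY(i, j) = st;
      }
    }
  }

  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  // traceback; 0 in the path vectors marks a gap
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      pa.push_back(a[i - 1]); pb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      pa.push_back(a[i - 1]); pb.push_back(0);
      --i; state = prev;
    } else {
      int prev = tbY(i, j);
      pa.push_back(0); pb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
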