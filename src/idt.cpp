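#include <Rcpp.h>
using namespace Rcpp;

// Dispersion-threshold (I-DT) window finder.
//
// Scans each maximal run of position-valid samples left to right. From a
// window start i it grows the end j while every sample in [i..j] stays
// within `disp_cm` (maximum pairwise Euclidean distance) of every other;
// when growth stops, the window is emitted as a fixation if its duration
// (t[j] - t[i] + period_ms) reaches `min_ms`, and scanning resumes at j+1;
// otherwise the start advances by one sample. A position-invalid sample
// always terminates the current window.
//
// Returns 1-based start/end sample indices of the detected fixations.
// [[Rcpp::export]]
DataFrame idt_windows_cpp(NumericVector t_ms, NumericVector x, NumericVector y,
                          LogicalVector valid, double disp_cm, double min_ms,
                          double period_ms) {
  int n = t_ms.size();
  std::vector<int> starts, ends;
  double d2 = disp_cm * disp_cm;
  int a = 0;
  while (a < n) {
    if (!valid[a]) { ++a; continue; }
    int b = a;
    while (b + 1 < n && valid[b + 1]) ++b;   // valid segment [a, b]
    int i = a, j = a;
    while (i <= b) {
      // grow: candidate j+1 must lie within disp of all current members
      while (j + 1 <= b) {
        bool ok = true;
        for (int k = i; k <= j; ++k) {
          double dx = x[j + 1] - x[k], dy = y[j + 1] - y[k];
          if (dx * dx + dy * dy > d2) { ok = false; break; }
        }
        if (!ok) break;
        ++j;
      }
      double dur = t_ms[j] - t_ms[i] + period_ms;
      if (dur >= min_ms - 1e-9) {
        starts.push_back(i + 1);
        ends.push_back(j + 1);
        i = j + 1;
        j = i;
      } else {
        ++i;
        if (j < i) j = i;
      }
    }
    a = b + 1;
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends);
}
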