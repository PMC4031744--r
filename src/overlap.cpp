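#include <Rcpp.h>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Longest suffix(a)-prefix(b) overlap with at most
// floor(max_mismatch_frac * olen) mismatches.  Returns 0 length if none.
static void best_sp(const std::string& a, const std::string& b,
                    int min_overlap, double max_frac,
                    int& best_len, int& best_mm) {
  best_len = 0; best_mm = 0;
  int la = (int)a.size(), lb = (int)b.size();
  int maxo = std::min(la, lb);
  for (int o = maxo; o >= min_overlap; --o) {
    int allowed = (int)(max_frac * o);
    int mm = 0;
    const char* pa = a.data() + (la - o);
    const char* pb = b.data();
    bool ok = true;
    for (int i = 0; i < o; ++i) {
      if (pa[i] != pb[i] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) { best_len = o; best_mm = mm; return; }  // longest first
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// The four suffix-prefix configurations between sequences a and b:
//   1: a -> b        2: b -> a        3: a -> rc(b)        4: rc(b) -> a
// Returns, per configuration, the longest admissible overlap (0 = none).
// [[Rcpp::export(name = ".overlap_pair_cpp")]]
IntegerMatrix overlap_pair_cpp(std::string a, std::string b,
                               int min_overlap, double max_mismatch_frac) {
  std::string rb = revcomp(b);
  IntegerMatrix out(4, 2);
  int len, mm;
  best_sp(a, b, min_overlap, max_mismatch_frac, len, mm);
  out(0, 0) = len; out(0, 1) = mm;
  best_sp(b, a, min_overlap, max_mismatch_frac, len, mm);
  out(1, 0) = len; out(1, 1) = mm;
  best_sp(a, rb, min_overlap, max_mismatch_frac, len, mm);
  out(2, 0) = len; out(2, 1) = mm;
  best_sp(rb, a, min_overlap, max_mismatch_frac, len, mm);
  out(3, 0) = len; out(3, 1) = mm;
  return out;
}
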