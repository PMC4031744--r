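#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3.  Encoded order == lexicographic order
// for equal-length k-mers, which lets us sort numerically and decode in
// string order.  k is capped at 31 so a k-mer fits one uint64.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static const char BIT2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BIT2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Append canonical codes of every valid (N-free) window of seq to out.
static void canonical_codes(const char* seq, int len, int k,
                            std::vector<uint64_t>& out) {
  if (len < k) return;
  uint64_t fwd = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift_rc = 2 * (k - 1);
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < len; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid >= k) out.push_back(std::min(fwd, rc));
  }
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    canonical_codes(s, (int)LENGTH(STRING_ELT(seqs, i)), k, codes);
  }
  std::sort(codes.begin(), codes.end());
  // run-length encode
  std::vector<uint64_t> keys;
  std::vector<int> counts;
  for (size_t i = 0; i < codes.size();) {
    size_t j = i;
    while (j < codes.size() && codes[j] == codes[i]) ++j;
    keys.push_back(codes[i]);
    counts.push_back((int)(j - i));
    i = j;
  }
  CharacterVector kmers(keys.size());
  IntegerVector cnt(counts.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = decode_kmer(keys[i], k);
    cnt[i] = counts[i];
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Membership of sorted a in sorted b by a single two-pointer merge pass.
// [[Rcpp::export(name = ".sorted_member_cpp")]]
LogicalVector sorted_member_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  LogicalVector out(na);
  R_xlen_t j = 0;
  for (R_xlen_t i = 0; i < na; ++i) {
    const char* ai = CHAR(STRING_ELT(a, i));
    while (j < nb && strcmp(CHAR(STRING_ELT(b, j)), ai) < 0) ++j;
    out[i] = (j < nb && strcmp(CHAR(STRING_ELT(b, j)), ai) == 0);
  }
  return out;
}

// For each read, the distinct candidate k-mers (canonical) it contains.
// Returns indices (1-based) of reads with >=1 hit and their matched k-mers.
// [[Rcpp::export(name = ".kmer_hits_cpp")]]
List kmer_hits_cpp(CharacterVector seqs, int k, CharacterVector candidates) {
  std::unordered_set<uint64_t> cand;
  cand.reserve(candidates.size() * 2 + 1);
  for (R_xlen_t i = 0; i < candidates.size(); ++i) {
    const char* s = CHAR(STRING_ELT(candidates, i));
    std::vector<uint64_t> c;
    canonical_codes(s, (int)LENGTH(STRING_ELT(candidates, i)), k, c);
    if (c.size() == 1) cand.insert(c[0]);
  }
  std::vector<int> idx;
  std::vector<std::vector<uint64_t>> matches;
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    codes.clear();
    const char* s = CHAR(STRING_ELT(seqs, i));
    canonical_codes(s, (int)LENGTH(STRING_ELT(seqs, i)), k, codes);
    std::vector<uint64_t> hit;
    for (uint64_t c : codes)
      if (cand.count(c)) hit.push_back(c);
    if (!hit.empty()) {
      std::sort(hit.begin(), hit.end());
      hit.erase(std::unique(hit.begin(), hit.end()), hit.end());
      idx.push_back((int)i + 1);
      matches.push_back(hit);
    }
  }
  List mt(matches.size());
  for (size_t i = 0; i < matches.size(); ++i) {
    CharacterVector m(matches[i].size());
    for (size_t j = 0; j < matches[i].size(); ++j)
      m[j] = decode_kmer(matches[i][j], k);
    mt[i] = m;
  }
  return List::create(_["index"] = wrap(idx), _["matches"] = mt);
}
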