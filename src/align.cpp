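#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---- local affine-gap alignment (Gotoh) with traceback ---------------------
//
// Scores: match, mismatch, gap open (first gapped base), gap extend (each
// further base).  CIGAR is relative to (query, target): M consumes both,
// I consumes query only, D consumes target only.

struct Aln {
  int score = 0;
  int qstart = 0, qend = 0;  // 0-based half-open on query
  int tstart = 0, tend = 0;  // 0-based half-open on target
  int matches = 0, columns = 0;
  std::string cigar;
};

static const int8_t TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3;

static Aln gotoh_local(const std::string& q, const std::string& t,
                       int match, int mismatch, int gapopen, int gapext) {
  const int m = (int)q.size(), n = (int)t.size();
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);  // gap in query (D)
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);  // gap in target (I)
  std::vector<int8_t> TB((size_t)(m + 1) * (n + 1), TB_STOP);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] + gapopen, E[at(i, j - 1)] + gapext);
      int f = std::max(H[at(i - 1, j)] + gapopen, F[at(i - 1, j)] + gapext);
      int s = (q[i - 1] == t[j - 1]) ? match : mismatch;
      int d = H[at(i - 1, j - 1)] + s;
      int h = std::max(0, std::max(d, std::max(e, f)));
      H[at(i, j)] = h;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      TB[at(i, j)] = (h == 0) ? TB_STOP
                   : (h == d) ? TB_DIAG
                   : (h == e) ? TB_LEFT
                              : TB_UP;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  Aln a;
  a.score = best;
  if (best == 0) return a;
  // traceback (greedy on H; adequate for the short, high-identity
  // alignments this pipeline produces)
  int i = bi, j = bj;
  std::string ops;
  while (i > 0 && j > 0 && TB[at(i, j)] != TB_STOP) {
    int8_t tb = TB[at(i, j)];
    if (tb == TB_DIAG) {
      ops.push_back('M');
      if (q[i - 1] == t[j - 1]) a.matches++;
      --i; --j;
    } else if (tb == TB_LEFT) {
      // gap in query: consume target; walk left while extension beats reopening
      while (j > 1 && E[at(i, j)] == E[at(i, j - 1)] + gapext) {
        ops.push_back('D'); --j;
      }
      ops.push_back('D'); --j;
    } else {
      while (i > 1 && F[at(i, j)] == F[at(i - 1, j)] + gapext) {
        ops.push_back('I'); --i;
      }
      ops.push_back('I'); --i;
    }
  }
  a.qstart = i; a.qend = bi;
  a.tstart = j; a.tend = bj;
  a.columns = (int)ops.size();
  std::reverse(ops.begin(), ops.end());
  // run-length encode into CIGAR
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t r = p;
    while (r < ops.size() && ops[r] == ops[p]) ++r;
    cig += std::to_string(r - p);
    cig.push_back(ops[p]);
    p = r;
  }
  a.cigar = cig;
  return a;
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

// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string query, std::string target,
                     int match = 1, int mismatch = -2,
                     int gapopen = -4, int gapext = -1) {
  Aln a = gotoh_local(query, target, match, mismatch, gapopen, gapext);
  return List::create(_["score"] = a.score, _["qstart"] = a.qstart,
                      _["qend"] = a.qend, _["tstart"] = a.tstart,
                      _["tend"] = a.tend, _["matches"] = a.matches,
                      _["columns"] = a.columns, _["cigar"] = a.cigar);
}

// Align each query (both orientations) locally to one target; report the
// better orientation per query.
// [[Rcpp::export(name = ".align_to_target_cpp")]]
DataFrame align_to_target_cpp(CharacterVector queries, std::string target,
                              int match = 1, int mismatch = -2,
                              int gapopen = -4, int gapext = -1) {
  int nq = queries.size();
  CharacterVector strand(nq), cigar(nq);
  IntegerVector score(nq), qs(nq), qe(nq), ts(nq), te(nq), mat(nq), col(nq);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    Aln f = gotoh_local(q, target, match, mismatch, gapopen, gapext);
    Aln r = gotoh_local(revcomp(q), target, match, mismatch, gapopen, gapext);
    bool use_r = r.score > f.score;
    const Aln& a = use_r ? r : f;
    strand[i] = use_r ? "-" : "+";
    score[i] = a.score; qs[i] = a.qstart; qe[i] = a.qend;
    ts[i] = a.tstart; te[i] = a.tend; mat[i] = a.matches;
    col[i] = a.columns; cigar[i] = a.cigar;
  }
  return DataFrame::create(_["strand"] = strand, _["score"] = score,
                           _["qstart"] = qs, _["qend"] = qe,
                           _["tstart"] = ts, _["tend"] = te,
                           _["matches"] = mat, _["columns"] = col,
                           _["cigar"] = cigar,
                           _["stringsAsFactors"] = false);
}

// ---- seeded whole-reference alignment --------------------------------------

struct RefIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  int k;
  // forward k-mer code -> packed (seq << 40 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> pos;
};

static inline int base2bit_a(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export(name = ".ref_index_cpp")]]
SEXP ref_index_cpp(CharacterVector seqs, int k) {
  RefIndex* idx = new RefIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    idx->names.push_back(as<std::string>(nm[s]));
    idx->seqs.push_back(as<std::string>(seqs[s]));
    const std::string& ref = idx->seqs.back();
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < ref.size(); ++i) {
      int b = base2bit_a(ref[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        idx->pos[code].push_back(((uint64_t)s << 40) | (uint64_t)(i - k + 1));
    }
  }
  XPtr<RefIndex> p(idx, true);
  return p;
}

// All seeded local alignments of query against the indexed reference, both
// strands.  Seed hits on one reference sequence are clustered by diagonal;
// each cluster is extended by local alignment of the query against the
// clamped reference window.
// [[Rcpp::export(name = ".seed_align_cpp")]]
DataFrame seed_align_cpp(SEXP idx_ptr, std::string query,
                         int match = 1, int mismatch = -2,
                         int gapopen = -4, int gapext = -1,
                         int max_kmer_hits = 200, int diag_band = 24,
                         int pad = 32) {
  XPtr<RefIndex> idx(idx_ptr);
  const int k = idx->k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  std::vector<std::string> o_ref;
  std::vector<std::string> o_strand, o_cigar;
  std::vector<int> o_rs, o_re, o_qs, o_qe, o_score, o_mat, o_col;

  for (int strand = 0; strand < 2; ++strand) {
    std::string qs = strand ? revcomp(query) : query;
    if ((int)qs.size() < k) continue;
    std::vector<std::array<int64_t, 2>> hv;  // seed hits as {seq, diagonal}
    uint64_t code = 0;
    int valid = 0;
    for (size_t j = 0; j < qs.size(); ++j) {
      int b = base2bit_a(qs[j]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid < k) continue;
      auto it = idx->pos.find(code);
      if (it == idx->pos.end()) continue;
      if ((int)it->second.size() > max_kmer_hits) continue;
      int64_t qpos = (int64_t)j - k + 1;
      for (uint64_t packed : it->second) {
        int64_t s = (int64_t)(packed >> 40);
        int64_t p = (int64_t)(packed & ((1ULL << 40) - 1));
        hv.push_back({s, p - qpos});
      }
    }
    if (hv.empty()) continue;
    std::sort(hv.begin(), hv.end());
    // cluster consecutive diagonals within diag_band on the same sequence
    size_t i0 = 0;
    while (i0 < hv.size()) {
      size_t i1 = i0 + 1;
      while (i1 < hv.size() && hv[i1][0] == hv[i0][0] &&
             hv[i1][1] - hv[i1 - 1][1] <= diag_band)
        ++i1;
      int s = (int)hv[i0][0];
      int64_t dmin = hv[i0][1], dmax = hv[i1 - 1][1];
      const std::string& ref = idx->seqs[s];
      int64_t ws = std::max<int64_t>(0, dmin - pad);
      int64_t we = std::min<int64_t>((int64_t)ref.size(),
                                     dmax + (int64_t)qs.size() + pad);
      Aln a = gotoh_local(qs, ref.substr(ws, we - ws),
                          match, mismatch, gapopen, gapext);
      if (a.score > 0) {
        o_ref.push_back(idx->names[s]);
        o_strand.push_back(strand ? "-" : "+");
        o_rs.push_back((int)(ws + a.tstart));
        o_re.push_back((int)(ws + a.tend));
        o_qs.push_back(a.qstart);
        o_qe.push_back(a.qend);
        o_score.push_back(a.score);
        o_mat.push_back(a.matches);
        o_col.push_back(a.columns);
        o_cigar.push_back(a.cigar);
      }
      i0 = i1;
    }
  }
  return DataFrame::create(_["ref"] = wrap(o_ref), _["strand"] = wrap(o_strand),
                           _["rstart"] = wrap(o_rs), _["rend"] = wrap(o_re),
                           _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
                           _["score"] = wrap(o_score),
                           _["matches"] = wrap(o_mat),
                           _["columns"] = wrap(o_col),
                           _["cigar"] = wrap(o_cigar),
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
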