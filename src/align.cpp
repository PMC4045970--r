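// Seed-and-verify tag aligner: exact k-mer seeds over the reference plus
// banded verification under a mismatch/indel budget (<=2 mismatches,
// <=2 indel bases by default, matching the marker definition). Alignment
// score = mismatches + 2 * indel bases; a hit is "unique" only when one
// locus attains a strictly better score than every other.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

struct RefIndex {
  std::vector<std::string> seqs;
  std::vector<uint64_t> keys;   // sorted seed keys
  std::vector<uint32_t> sid;    // sequence id per entry
  std::vector<uint32_t> pos;    // 0-based position per entry
  int k = 23;
};

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static bool encode_kmer(const char* s, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP radmap_build_index(CharacterVector seqs, int k = 23) {
  XPtr<RefIndex> idx(new RefIndex(), true);
  idx->k = k;
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    if ((R_xlen_t)idx->seqs.back().size() >= k)
      total += idx->seqs.back().size() - k + 1;
  }
  std::vector<std::pair<uint64_t, uint64_t>> entries;  // key, (sid<<32)|pos
  entries.reserve(total);
  for (size_t s = 0; s < idx->seqs.size(); ++s) {
    const std::string& str = idx->seqs[s];
    if ((int)str.size() < k) continue;
    for (size_t p = 0; p + k <= str.size(); ++p) {
      uint64_t key;
      if (encode_kmer(str.c_str() + p, k, key))
        entries.emplace_back(key, ((uint64_t)s << 32) | (uint64_t)p);
    }
  }
  std::sort(entries.begin(), entries.end());
  idx->keys.resize(entries.size());
  idx->sid.resize(entries.size());
  idx->pos.resize(entries.size());
  for (size_t i = 0; i < entries.size(); ++i) {
    idx->keys[i] = entries[i].first;
    idx->sid[i] = (uint32_t)(entries[i].second >> 32);
    idx->pos[i] = (uint32_t)(entries[i].second & 0xffffffffULL);
  }
  return idx;
}

// [[Rcpp::export]]
double radmap_index_size(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  return (double)idx->keys.size();
}

struct Hit {
  int sid;
  long pos;       // leftmost reference coordinate of the candidate window
  int strand;     // 0 = +, 1 = -
  int mm;
  int gap;
  int score() const { return mm + 2 * gap; }
};

// Verification of tag against ref anchored at `start` (tag base 0 maps to
// ref[start] in the zero-offset state). The model mirrors the marker
// definition: up to max_mm mismatches plus at most ONE contiguous indel
// event of up to max_indel bases. Degenerate adjacent insertion+deletion
// pairs (which would let any substitution masquerade as a 2-base gap) are
// therefore impossible. Returns best (mm, gap) within budget, or mm < 0.
static void verify(const std::string& ref, long start, const char* tag,
                   int L, int max_mm, int max_indel, int& best_mm,
                   int& best_gap) {
  const int INF = 1 << 20;
  long rlen = (long)ref.size();
  auto mis = [&](long q, int i) -> int {
    return (q < 0 || q >= rlen || ref[q] != tag[i]) ? 1 : 0;
  };
  // prefix mismatches on the zero diagonal: pre[p] = mm of tag[0..p)
  std::vector<int> pre(L + 1, 0);
  for (int i = 0; i < L; ++i) pre[i + 1] = pre[i] + mis(start + i, i);
  best_mm = -1; best_gap = 0;
  int best_score = INF;
  if (pre[L] <= max_mm) { best_mm = pre[L]; best_gap = 0; best_score = pre[L]; }
  // one indel event of g bases at split p
  std::vector<int> suf(L + 1, 0);
  for (int g = 1; g <= max_indel; ++g) {
    // deletion in tag (ref longer): tag[p..L) vs ref[start+p+g ..)
    suf[L] = 0;
    for (int i = L - 1; i >= 0; --i) suf[i] = suf[i + 1] + mis(start + i + g, i);
    for (int p = 0; p <= L; ++p) {
      int mm = pre[p] + suf[p];
      int sc = mm + 2 * g;
      if (mm <= max_mm && sc < best_score) {
        best_score = sc; best_mm = mm; best_gap = g;
      }
    }
    // insertion in tag (tag longer): tag[p+g..L) vs ref[start+p ..)
    suf[L] = 0;
    for (int i = L - 1; i >= g; --i) suf[i] = suf[i + 1] + mis(start + i - g, i);
    for (int p = 0; p + g <= L; ++p) {
      int mm = pre[p] + suf[p + g];
      int sc = mm + 2 * g;
      if (mm <= max_mm && sc < best_score) {
        best_score = sc; best_mm = mm; best_gap = g;
      }
    }
  }
}

static void revcomp_str(const std::string& in, std::string& out) {
  out.resize(in.size());
  for (size_t i = 0; i < in.size(); ++i) {
    char c = in[in.size() - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break; case 'C': r = 'G'; break;
      case 'G': r = 'C'; break; case 'T': r = 'A'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
}

static void align_one(const RefIndex& idx, const std::string& tag, int max_mm,
                      int max_indel, std::vector<Hit>& hits) {
  hits.clear();
  int k = idx.k;
  int L = (int)tag.size();
  std::string rc;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& t = (strand == 0) ? tag : (revcomp_str(tag, rc), rc);
    // candidate starts from seed hits
    std::vector<std::pair<int, long>> cands;
    std::vector<int> offsets;
    for (int o = 0; o + k <= L; o += k) offsets.push_back(o);
    if (!offsets.empty() && offsets.back() + k < L) offsets.push_back(L - k);
    for (int o : offsets) {
      uint64_t key;
      if (!encode_kmer(t.c_str() + o, k, key)) continue;
      auto lo = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
      auto hi = std::upper_bound(idx.keys.begin(), idx.keys.end(), key);
      for (auto it = lo; it != hi; ++it) {
        size_t e = it - idx.keys.begin();
        cands.emplace_back((int)idx.sid[e], (long)idx.pos[e] - o);
      }
    }
    // an indel between the seed and the tag start shifts the anchor by up
    // to max_indel bases; widen each candidate so the true anchor (where
    // the DP starts in the zero-offset state) is always tried
    size_t n_raw = cands.size();
    for (size_t ci = 0; ci < n_raw; ++ci) {
      for (int d = -max_indel; d <= max_indel; ++d) {
        if (d != 0) cands.emplace_back(cands[ci].first, cands[ci].second + d);
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    for (auto& c : cands) {
      int mm, gap;
      verify(idx.seqs[c.first], c.second, t.c_str(), L, max_mm, max_indel,
             mm, gap);
      if (mm >= 0) {
        Hit h; h.sid = c.first; h.pos = c.second; h.strand = strand;
        h.mm = mm; h.gap = gap;
        hits.push_back(h);
      }
    }
  }
  // merge hits within 3 bp on the same (sid, strand), keep best score
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.sid != b.sid) return a.sid < b.sid;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.pos < b.pos;
  });
  std::vector<Hit> merged;
  for (auto& h : hits) {
    if (!merged.empty() && merged.back().sid == h.sid &&
        merged.back().strand == h.strand && h.pos - merged.back().pos <= 3) {
      if (h.score() < merged.back().score()) merged.back() = h;
    } else {
      merged.push_back(h);
    }
  }
  hits.swap(merged);
}

// [[Rcpp::export]]
DataFrame radmap_align_tags(SEXP xp, CharacterVector tags, int max_mm = 2,
                            int max_indel = 2) {
  XPtr<RefIndex> idx(xp);
  R_xlen_t n = tags.size();
  IntegerVector sid(n), pos(n), mm(n), gap(n), nhits(n);
  CharacterVector strand(n), status(n);
  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string tag = as<std::string>(tags[i]);
    align_one(*idx, tag, max_mm, max_indel, hits);
    nhits[i] = (int)hits.size();
    if (hits.empty()) {
      sid[i] = NA_INTEGER; pos[i] = NA_INTEGER; mm[i] = NA_INTEGER;
      gap[i] = NA_INTEGER; strand[i] = NA_STRING; status[i] = "unaligned";
      continue;
    }
    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      return a.score() < b.score();
    });
    bool unique = hits.size() == 1 || hits[1].score() > hits[0].score();
    const Hit& h = hits[0];
    sid[i] = h.sid + 1; pos[i] = (int)h.pos; mm[i] = h.mm; gap[i] = h.gap;
    strand[i] = h.strand == 0 ? "+" : "-";
    status[i] = unique ? "unique" : "ambiguous";
  }
  return DataFrame::create(_["seq_idx"] = sid, _["pos"] = pos,
                           _["strand"] = strand, _["mm"] = mm,
                           _["indel"] = gap, _["n_hits"] = nhits,
                           _["status"] = status,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame radmap_align_hits(SEXP xp, CharacterVector tags, int max_mm = 2,
                            int max_indel = 2) {
  XPtr<RefIndex> idx(xp);
  std::vector<int> tid, sid, mm, gap;
  std::vector<long> pos;
  std::vector<std::string> strand;
  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < tags.size(); ++i) {
    std::string tag = as<std::string>(tags[i]);
    align_one(*idx, tag, max_mm, max_indel, hits);
    for (auto& h : hits) {
      tid.push_back((int)i + 1);
      sid.push_back(h.sid + 1);
      pos.push_back(h.pos);
      strand.push_back(h.strand == 0 ? "+" : "-");
      mm.push_back(h.mm);
      gap.push_back(h.gap);
    }
  }
  return DataFrame::create(_["tag_idx"] = wrap(tid), _["seq_idx"] = wrap(sid),
                           _["pos"] = wrap(pos), _["strand"] = wrap(strand),
                           _["mm"] = wrap(mm), _["indel"] = wrap(gap),
                           _["stringsAsFactors"] = false);
}
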