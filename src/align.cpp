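// Seed-and-extend Hamming alignment of short tags against a small labeled
// reference universe, plus the hierarchical source-class / HERV-family
// classification rule. References are passed id-sorted from R so that the
// reference index order coincides with lexicographic id order, which makes
// tie-breaking deterministic.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <climits>
#include <cstdint>

using namespace Rcpp;

namespace {

// source-class codes shared with R: 0 RRNA, 1 HOST_TX, 2 NUCLEAR, 3 MTDNA,
// 4 MICROBIAL, 5 HERV. Category codes add 6 HERV_AMBIGUOUS, 7 UNASSIGNED.
const int TIER_OF_CLASS[6] = {0, 1, 1, 2, 3, 4};

inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

struct Refs {
  std::vector<uint8_t> seq;     // all references concatenated, 2-bit codes
  std::vector<int> start;       // per-reference offset into seq
  std::vector<int> len;
  std::vector<int> posref;      // global position -> reference index
};

Refs pack_refs(const CharacterVector& ref_seqs) {
  Refs R;
  R_xlen_t nref = ref_seqs.size();
  size_t total = 0;
  for (R_xlen_t i = 0; i < nref; ++i) total += LENGTH(STRING_ELT(ref_seqs, i));
  R.seq.reserve(total);
  R.posref.reserve(total);
  for (R_xlen_t i = 0; i < nref; ++i) {
    const char* s = CHAR(STRING_ELT(ref_seqs, i));
    int n = LENGTH(STRING_ELT(ref_seqs, i));
    R.start.push_back(static_cast<int>(R.seq.size()));
    R.len.push_back(n);
    for (int j = 0; j < n; ++j) {
      int b = enc(s[j]);
      if (b < 0) stop("reference %d contains a non-ACGT base", (int)(i + 1));
      R.seq.push_back(static_cast<uint8_t>(b));
      R.posref.push_back(static_cast<int>(i));
    }
  }
  return R;
}

typedef std::unordered_map<uint64_t, std::vector<int> > SeedIndex;

SeedIndex build_index(const Refs& R, int k) {
  SeedIndex idx;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (size_t r = 0; r < R.start.size(); ++r) {
    int s = R.start[r], n = R.len[r];
    if (n < k) continue;
    uint64_t key = 0;
    for (int j = 0; j < n; ++j) {
      key = ((key << 2) | R.seq[s + j]) & mask;
      if (j >= k - 1) idx[key].push_back(s + j - k + 1);
    }
  }
  return idx;
}

struct Hit {
  int ref, pos, strand, mm;   // pos 0-based on the reference; strand 0 '+', 1 '-'
};

inline bool hit_less(const Hit& a, const Hit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.ref != b.ref) return a.ref < b.ref;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand < b.strand;
}

std::vector<uint8_t> enc_tag(SEXP s, R_xlen_t i) {
  const char* c = CHAR(s);
  int n = LENGTH(s);
  std::vector<uint8_t> v(n);
  for (int j = 0; j < n; ++j) {
    int b = enc(c[j]);
    if (b < 0) stop("tag %d contains a non-ACGT base", (int)(i + 1));
    v[j] = static_cast<uint8_t>(b);
  }
  return v;
}

std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t j = 0; j < v.size(); ++j) r[v.size() - 1 - j] = 3 - v[j];
  return r;
}

// Collect every placement of the tag (both strands) with Hamming distance
// <= max_mm. Seeds of length k are looked up at non-overlapping offsets
// 0, k, 2k, ... plus the tail offset L-k; k <= floor(L/(max_mm+1)) makes
// this exhaustive by pigeonhole (some chunk must be mismatch-free).
void align_one(const Refs& R, const SeedIndex& idx, int k,
               const std::vector<uint8_t>& fwd,
               const std::vector<uint8_t>& rc,
               int max_mm,
               const std::vector<char>& class_ok,
               const IntegerVector& ref_class,
               std::vector<Hit>& out) {
  int L = static_cast<int>(fwd.size());
  std::unordered_set<int64_t> seen;
  int total = static_cast<int>(R.seq.size());
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<uint8_t>& t = (strand == 0) ? fwd : rc;
    for (int o = 0;; o += k) {
      if (o + k > L) o = L - k;               // tail chunk
      uint64_t key = 0;
      for (int j = 0; j < k; ++j) key = (key << 2) | t[o + j];
      SeedIndex::const_iterator it = idx.find(key);
      if (it != idx.end()) {
        const std::vector<int>& cand = it->second;
        for (size_t ci = 0; ci < cand.size(); ++ci) {
          int gstart = cand[ci] - o;
          if (gstart < 0 || gstart + L > total) continue;
          int r = R.posref[gstart];
          if (R.posref[gstart + L - 1] != r) continue;   // spans two references
          if (!class_ok[ref_class[r]]) continue;
          int64_t dedup = (static_cast<int64_t>(gstart) << 1) | strand;
          if (!seen.insert(dedup).second) continue;
          int mm = 0;
          const uint8_t* rs = &R.seq[gstart];
          for (int j = 0; j < L; ++j) {
            if (rs[j] != t[j] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            Hit h; h.ref = r; h.pos = gstart - R.start[r]; h.strand = strand; h.mm = mm;
            out.push_back(h);
          }
        }
      }
      if (o == L - k) break;
    }
  }
  std::sort(out.begin(), out.end(), hit_less);
}

int check_k(int k, int max_mm, int min_tag_len) {
  if (k < 1) stop("effective seed length must be >= 1");
  if (k > 31) k = 31;                         // 2-bit packing limit
  if (k > min_tag_len) stop("seed length exceeds tag length");
  (void)max_mm;
  return k;
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_align_tags(CharacterVector ref_seqs, IntegerVector ref_class,
                         CharacterVector tags, int k, int max_mm,
                         LogicalVector class_allowed) {
  Refs R = pack_refs(ref_seqs);
  int min_len = INT_MAX;
  for (R_xlen_t i = 0; i < tags.size(); ++i)
    min_len = std::min(min_len, LENGTH(STRING_ELT(tags, i)));
  k = check_k(k, max_mm, min_len);
  SeedIndex idx = build_index(R, k);
  std::vector<char> ok(6, 0);
  for (int c = 0; c < 6; ++c) ok[c] = class_allowed[c] ? 1 : 0;

  std::vector<int> tag_i, ref_i, pos, strand, mm;
  for (R_xlen_t i = 0; i < tags.size(); ++i) {
    std::vector<uint8_t> fwd = enc_tag(STRING_ELT(tags, i), i);
    std::vector<uint8_t> rc = revcomp(fwd);
    std::vector<Hit> hits;
    align_one(R, idx, k, fwd, rc, max_mm, ok, ref_class, hits);
    for (size_t h = 0; h < hits.size(); ++h) {
      tag_i.push_back(static_cast<int>(i + 1));
      ref_i.push_back(hits[h].ref + 1);
      pos.push_back(hits[h].pos);
      strand.push_back(hits[h].strand);
      mm.push_back(hits[h].mm);
    }
  }
  return DataFrame::create(_["tag"] = tag_i, _["ref"] = ref_i, _["pos"] = pos,
                           _["strand"] = strand, _["mm"] = mm);
}

// [[Rcpp::export]]
DataFrame cpp_classify_tags(CharacterVector ref_seqs, IntegerVector ref_class,
                            IntegerVector ref_family, int n_families,
                            IntegerVector ann_ref, IntegerVector ann_start,
                            IntegerVector ann_end, IntegerVector ann_label,
                            CharacterVector tags, int k, int max_mm, int margin) {
  Refs R = pack_refs(ref_seqs);
  int min_len = INT_MAX;
  for (R_xlen_t i = 0; i < tags.size(); ++i)
    min_len = std::min(min_len, LENGTH(STRING_ELT(tags, i)));
  k = check_k(k, max_mm, min_len);
  SeedIndex idx = build_index(R, k);
  std::vector<char> ok(6, 1);

  // per-reference annotation intervals for region-by-midpoint lookup
  std::vector<std::vector<int> > ann_of(ref_seqs.size());
  for (R_xlen_t a = 0; a < ann_ref.size(); ++a)
    ann_of[ann_ref[a] - 1].push_back(static_cast<int>(a));

  R_xlen_t n = tags.size();
  IntegerVector category(n), family(n), region(n), refout(n), posout(n),
      strandout(n), mmout(n);

  std::vector<int> fam_best(n_families);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::vector<uint8_t> fwd = enc_tag(STRING_ELT(tags, i), i);
    std::vector<uint8_t> rc = revcomp(fwd);
    int L = static_cast<int>(fwd.size());
    std::vector<Hit> hits;
    align_one(R, idx, k, fwd, rc, max_mm, ok, ref_class, hits);

    family[i] = NA_INTEGER; region[i] = NA_INTEGER; refout[i] = NA_INTEGER;
    posout[i] = NA_INTEGER; strandout[i] = NA_INTEGER; mmout[i] = NA_INTEGER;

    if (hits.empty()) { category[i] = 7; continue; }

    int tier = 5;
    for (size_t h = 0; h < hits.size(); ++h)
      tier = std::min(tier, TIER_OF_CLASS[ref_class[hits[h].ref]]);

    const Hit* best = 0;
    if (tier < 4) {
      int want_class = -1;
      if (tier == 1) {
        // transcriptome beats nuclear-genome-only within the host tier
        bool has_tx = false;
        for (size_t h = 0; h < hits.size(); ++h)
          if (ref_class[hits[h].ref] == 1) { has_tx = true; break; }
        want_class = has_tx ? 1 : 2;
      } else if (tier == 0) want_class = 0;
      else if (tier == 2) want_class = 3;
      else want_class = 4;
      category[i] = want_class;
      for (size_t h = 0; h < hits.size(); ++h)
        if (ref_class[hits[h].ref] == want_class) { best = &hits[h]; break; }
    } else {
      // HERV tier: unique best family with an ambiguity margin
      std::fill(fam_best.begin(), fam_best.end(), INT_MAX);
      for (size_t h = 0; h < hits.size(); ++h) {
        if (ref_class[hits[h].ref] != 5) continue;
        int f = ref_family[hits[h].ref] - 1;
        fam_best[f] = std::min(fam_best[f], hits[h].mm);
      }
      int d1 = INT_MAX, d2 = INT_MAX, f1 = -1, n_at_d1 = 0;
      for (int f = 0; f < n_families; ++f) {
        if (fam_best[f] < d1) { d2 = d1; d1 = fam_best[f]; f1 = f; n_at_d1 = 1; }
        else if (fam_best[f] == d1 && d1 != INT_MAX) { ++n_at_d1; d2 = d1; }
        else if (fam_best[f] < d2) d2 = fam_best[f];
      }
      bool unambiguous = (n_at_d1 == 1) &&
        (d2 == INT_MAX || d2 - d1 >= margin);
      if (unambiguous) {
        category[i] = 5;
        family[i] = f1 + 1;
        for (size_t h = 0; h < hits.size(); ++h) {
          const Hit& hh = hits[h];
          if (ref_class[hh.ref] == 5 && ref_family[hh.ref] - 1 == f1 && hh.mm == d1) {
            best = &hh; break;
          }
        }
        // region containing the midpoint of the aligned interval
        int mid = best->pos + L / 2;
        const std::vector<int>& anns = ann_of[best->ref];
        for (size_t a = 0; a < anns.size(); ++a) {
          int ai = anns[a];
          if (ann_start[ai] <= mid && mid < ann_end[ai]) {
            region[i] = ann_label[ai];
            break;
          }
        }
      } else {
        category[i] = 6;
        for (size_t h = 0; h < hits.size(); ++h)
          if (ref_class[hits[h].ref] == 5) { best = &hits[h]; break; }
      }
    }
    if (best) {
      refout[i] = best->ref + 1;
      posout[i] = best->pos;
      strandout[i] = best->strand;
      mmout[i] = best->mm;
    }
  }
  return DataFrame::create(_["category"] = category, _["family"] = family,
                           _["region"] = region, _["ref"] = refout,
                           _["pos"] = posout, _["strand"] = strandout,
                           _["mm"] = mmout);
}
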