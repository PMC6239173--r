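#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// One-mismatch short-read alignment with bowtie "-v" style semantics.
// Strategy: pigeonhole. For reads of length L >= 2k, a placement with at
// most one mismatch has an exact match of either the first or the last
// k-mer, so candidate start positions come from a k-mer index of the
// reference set and are then verified. Reads shorter than 2k or containing
// non-ACGT characters fall back to a full sliding-window scan.

static const int KIDX = 9; // index k-mer size; min supported read for the fast path is 18 nt

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N and friends: never matches
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement(s[i]);
  return out;
}

struct Hit {
  int ref;      // 0-based reference index
  int start;    // 0-based start on the plus strand of the reference
  bool minus;   // true if the read aligns to the minus strand
  int n_mm;     // 0 or 1
  int mm_off;   // reference offset of the mismatch (-1 if none)
  char mm_ref;  // reference base at the mismatch
  char mm_read; // aligned (plus-strand projected) read base at the mismatch
};

// verify window ref[start, start+L) against pattern; returns false if more
// than max_mm mismatches
static bool verify(const std::string& ref, int start, const std::string& pat,
                   int max_mm, Hit& h) {
  int L = (int) pat.size();
  if (start < 0 || start + L > (int) ref.size()) return false;
  int mm = 0, off = -1;
  for (int i = 0; i < L; ++i) {
    char rb = ref[start + i], pb = pat[i];
    if (rb != pb || rb == 'N') { // N never matches, even N vs N
      if (++mm > max_mm) return false;
      off = i;
    }
  }
  h.n_mm = mm;
  if (mm == 1) {
    h.mm_off = off;
    h.mm_ref = ref[start + off];
    h.mm_read = pat[off];
  } else {
    h.mm_off = -1; h.mm_ref = 0; h.mm_read = 0;
  }
  return true;
}

class KmerIndex {
public:
  std::unordered_map<uint32_t, std::vector<std::pair<int,int> > > map; // kmer -> (ref, pos)
  void build(const std::vector<std::string>& refs) {
    for (int r = 0; r < (int) refs.size(); ++r) {
      const std::string& s = refs[r];
      if ((int) s.size() < KIDX) continue;
      uint32_t key = 0; int valid = 0;
      for (int i = 0; i < (int) s.size(); ++i) {
        int c = base2code(s[i]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t) c) & ((1u << (2 * KIDX)) - 1u);
        if (++valid >= KIDX)
          map[key].push_back(std::make_pair(r, i - KIDX + 1));
      }
    }
  }
  const std::vector<std::pair<int,int> >* lookup(uint32_t key) const {
    std::unordered_map<uint32_t, std::vector<std::pair<int,int> > >::const_iterator
      it = map.find(key);
    return it == map.end() ? 0 : &it->second;
  }
};

static bool kmer_key(const std::string& s, int from, uint32_t& key) {
  key = 0;
  for (int i = from; i < from + KIDX; ++i) {
    int c = base2code(s[i]);
    if (c < 0) return false;
    key = (key << 2) | (uint32_t) c;
  }
  return true;
}

// gather candidate placements for one oriented pattern via the index
static void candidates_indexed(const KmerIndex& idx, const std::string& pat,
                               std::vector<std::pair<int,int> >& cand) {
  int L = (int) pat.size();
  uint32_t k1, k2;
  if (kmer_key(pat, 0, k1)) {
    const std::vector<std::pair<int,int> >* v = idx.lookup(k1);
    if (v) for (size_t i = 0; i < v->size(); ++i)
      cand.push_back(std::make_pair((*v)[i].first, (*v)[i].second));
  }
  int off2 = L - KIDX;
  if (kmer_key(pat, off2, k2)) {
    const std::vector<std::pair<int,int> >* v = idx.lookup(k2);
    if (v) for (size_t i = 0; i < v->size(); ++i)
      cand.push_back(std::make_pair((*v)[i].first, (*v)[i].second - off2));
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
}

// full scan of one oriented pattern against every reference window
static void scan_pattern(const std::vector<std::string>& refs,
                         const std::string& pat, int max_mm, bool minus,
                         std::vector<Hit>& hits) {
  int L = (int) pat.size();
  for (int r = 0; r < (int) refs.size(); ++r) {
    const std::string& ref = refs[r];
    int last = (int) ref.size() - L;
    for (int p = 0; p <= last; ++p) {
      Hit h; h.ref = r; h.start = p; h.minus = minus;
      if (verify(ref, p, pat, max_mm, h)) hits.push_back(h);
    }
  }
}

static void search_pattern(const KmerIndex& idx,
                           const std::vector<std::string>& refs,
                           const std::string& pat, int max_mm, bool minus,
                           std::vector<Hit>& hits) {
  int L = (int) pat.size();
  bool clean = true;
  for (int i = 0; i < L && clean; ++i)
    if (base2code(pat[i]) < 0) clean = false;
  if (L < 2 * KIDX || !clean) {
    // slow path: short reads or reads with N (a single N still tolerated as
    // the one mismatch by verify())
    scan_pattern(refs, pat, max_mm, minus, hits);
    return;
  }
  std::vector<std::pair<int,int> > cand;
  candidates_indexed(idx, pat, cand);
  for (size_t i = 0; i < cand.size(); ++i) {
    Hit h; h.ref = cand[i].first; h.start = cand[i].second; h.minus = minus;
    if (verify(refs[h.ref], h.start, pat, max_mm, h)) hits.push_back(h);
  }
}

// [[Rcpp::export]]
List cpp_align(CharacterVector reads, CharacterVector refs, int max_mm,
               bool both_strands) {
  if (max_mm < 0 || max_mm > 1) stop("max_mm must be 0 or 1");
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  idx.build(R);

  std::vector<int> o_read, o_ref, o_start, o_nmm, o_mmoff;
  std::vector<int> o_strand; // 1 = plus, -1 = minus
  std::vector<std::string> o_mmref, o_mmread;

  for (int i = 0; i < reads.size(); ++i) {
    std::string pat = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    search_pattern(idx, R, pat, max_mm, false, hits);
    if (both_strands) {
      std::string rc = revcomp(pat);
      search_pattern(idx, R, rc, max_mm, true, hits);
    }
    // best stratum: 0-mismatch hits suppress 1-mismatch hits for this read
    bool has0 = false;
    for (size_t j = 0; j < hits.size(); ++j)
      if (hits[j].n_mm == 0) { has0 = true; break; }
    for (size_t j = 0; j < hits.size(); ++j) {
      if (has0 && hits[j].n_mm > 0) continue;
      o_read.push_back(i + 1);
      o_ref.push_back(hits[j].ref + 1);
      o_start.push_back(hits[j].start);
      o_strand.push_back(hits[j].minus ? -1 : 1);
      o_nmm.push_back(hits[j].n_mm);
      o_mmoff.push_back(hits[j].mm_off);
      o_mmref.push_back(hits[j].n_mm ? std::string(1, hits[j].mm_ref) : std::string());
      o_mmread.push_back(hits[j].n_mm ? std::string(1, hits[j].mm_read) : std::string());
    }
  }
  return List::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["start"] = wrap(o_start), _["strand"] = wrap(o_strand),
    _["n_mm"] = wrap(o_nmm), _["mm_offset"] = wrap(o_mmoff),
    _["mm_ref"] = wrap(o_mmref), _["mm_read"] = wrap(o_mmread));
}

// Naive O(N*M) sliding-window scan used as the oracle for the indexed
// search: every window of every reference is verified directly, with no
// k-mer index and no pigeonhole shortcut. Same output contract as
// cpp_align (best-stratum reporting included).
// [[Rcpp::export]]
List cpp_align_scan(CharacterVector reads, CharacterVector refs, int max_mm,
                    bool both_strands) {
  if (max_mm < 0 || max_mm > 1) stop("max_mm must be 0 or 1");
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);

  std::vector<int> o_read, o_ref, o_start, o_nmm, o_mmoff;
  std::vector<int> o_strand;
  std::vector<std::string> o_mmref, o_mmread;

  for (int i = 0; i < reads.size(); ++i) {
    std::string pat = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    scan_pattern(R, pat, max_mm, false, hits);
    if (both_strands) {
      std::string rc = revcomp(pat);
      scan_pattern(R, rc, max_mm, true, hits);
    }
    bool has0 = false;
    for (size_t j = 0; j < hits.size(); ++j)
      if (hits[j].n_mm == 0) { has0 = true; break; }
    for (size_t j = 0; j < hits.size(); ++j) {
      if (has0 && hits[j].n_mm > 0) continue;
      o_read.push_back(i + 1);
      o_ref.push_back(hits[j].ref + 1);
      o_start.push_back(hits[j].start);
      o_strand.push_back(hits[j].minus ? -1 : 1);
      o_nmm.push_back(hits[j].n_mm);
      o_mmoff.push_back(hits[j].mm_off);
      o_mmref.push_back(hits[j].n_mm ? std::string(1, hits[j].mm_ref) : std::string());
      o_mmread.push_back(hits[j].n_mm ? std::string(1, hits[j].mm_read) : std::string());
    }
  }
  return List::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["start"] = wrap(o_start), _["strand"] = wrap(o_strand),
    _["n_mm"] = wrap(o_nmm), _["mm_offset"] = wrap(o_mmoff),
    _["mm_ref"] = wrap(o_mmref), _["mm_read"] = wrap(o_mmread));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
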