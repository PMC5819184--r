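// Unique read-to-TE-subfamily assignment.
//
// Each mate is scored independently against every reference with an
// ungapped, k-mer-seeded diagonal alignment: seeds propose diagonals, the
// whole read is then scored on each candidate diagonal (match +1,
// mismatch -1), clipped at reference ends.  A mate is assigned to the
// single best-scoring reference only if it passes the identity and
// aligned-fraction thresholds and beats the runner-up reference by at
// least the uniqueness margin.  Reverse complements are always tried.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int SCORE_NONE = INT32_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and friends: never match anything
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? -1 : 3 - c;
  }
  return r;
}

// one shared k-mer index over all references: kmer -> packed (ref, pos)
struct CombinedIndex {
  std::vector<std::vector<int> > refs;
  std::unordered_map<uint64_t, std::vector<uint64_t> > kmers;
};

static void index_refs(CombinedIndex& idx, int k) {
  for (size_t r = 0; r < idx.refs.size(); ++r) {
    const std::vector<int>& s = idx.refs[r];
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;  // length of current valid (ACGT-only) run
    for (int i = 0; i < n; ++i) {
      if (s[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)s[i]) & mask;
      if (++run >= k)
        idx.kmers[key].push_back(((uint64_t)r << 32) |
                                 (uint64_t)(i - k + 1));
    }
  }
}

struct Best {
  int score, alen, matches, strand;  // strand: 0 fwd, 1 rev
  Best() : score(SCORE_NONE), alen(0), matches(0), strand(0) {}
};

// Score the full read on one diagonal, clipped at reference ends.
// diag = ref_pos - read_pos.
static inline void score_diag(const std::vector<int>& read,
                              const std::vector<int>& ref,
                              int diag, int strand, Best& best) {
  const int L = (int)read.size(), n = (int)ref.size();
  int i0 = std::max(0, -diag);
  int i1 = std::min(L, n - diag);  // exclusive
  int alen = i1 - i0;
  if (alen <= 0) return;
  int matches = 0;
  for (int i = i0; i < i1; ++i)
    if (read[i] >= 0 && read[i] == ref[i + diag]) ++matches;
  int score = 2 * matches - alen;
  if (score > best.score) {
    best.score = score; best.alen = alen; best.matches = matches;
    best.strand = strand;
  }
}

// seed one read strand against the combined index and score every
// distinct (ref, diagonal) candidate into the per-reference bests
static void seed_and_score(const std::vector<int>& read,
                           const CombinedIndex& idx, int k, int strand,
                           std::vector<Best>& best,
                           std::vector<int64_t>& hit_buf) {
  const int L = (int)read.size();
  if (L < k) return;
  hit_buf.clear();
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < L; ++i) {
    if (read[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)read[i]) & mask;
    if (++run < k) continue;
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
        it = idx.kmers.find(key);
    if (it == idx.kmers.end()) continue;
    const std::vector<uint64_t>& pos = it->second;
    for (size_t j = 0; j < pos.size(); ++j) {
      int r = (int)(pos[j] >> 32);
      int p = (int)(pos[j] & 0xffffffffULL);
      // pack (ref, diag) keeping sort order; diag >= -(L-1) > -2^20
      hit_buf.push_back(((int64_t)r << 32) |
                        (int64_t)(p - (i - k + 1) + (1 << 20)));
    }
  }
  if (hit_buf.empty()) return;
  std::sort(hit_buf.begin(), hit_buf.end());
  hit_buf.erase(std::unique(hit_buf.begin(), hit_buf.end()),
                hit_buf.end());
  for (size_t h = 0; h < hit_buf.size(); ++h) {
    int r = (int)(hit_buf[h] >> 32);
    int diag = (int)(hit_buf[h] & 0xffffffffLL) - (1 << 20);
    score_diag(read, idx.refs[r], diag, strand, best[r]);
  }
}

// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, CharacterVector refs,
                      int k, double min_identity, double min_aligned_frac,
                      int margin) {
  const int nref = refs.size(), nread = reads.size();
  CombinedIndex idx;
  idx.refs.resize(nref);
  for (int r = 0; r < nref; ++r)
    idx.refs[r] = encode(as<std::string>(refs[r]));
  index_refs(idx, k);
  IntegerVector family(nread), aligned(nread), score(nread), second(nread);
  NumericVector identity(nread);
  IntegerVector strand(nread);
  std::vector<int64_t> hit_buf;
  std::vector<Best> bests(nref);
  for (int q = 0; q < nread; ++q) {
    std::vector<int> fwd = encode(as<std::string>(reads[q]));
    std::vector<int> rev = revcomp(fwd);
    const int L = (int)fwd.size();
    std::fill(bests.begin(), bests.end(), Best());
    seed_and_score(fwd, idx, k, 0, bests, hit_buf);
    seed_and_score(rev, idx, k, 1, bests, hit_buf);
    int best_ref = -1, best_score = SCORE_NONE, second_score = SCORE_NONE;
    Best best_aln;
    for (int r = 0; r < nref; ++r) {
      const Best& b = bests[r];
      if (b.score > best_score) {
        second_score = best_score;
        best_score = b.score; best_ref = r; best_aln = b;
      } else if (b.score > second_score) {
        second_score = b.score;
      }
    }
    int fam = 0, alen = 0, strd = NA_INTEGER;
    double ident = NA_REAL;
    if (best_ref >= 0 && best_score > SCORE_NONE) {
      alen = best_aln.alen;
      ident = best_aln.alen > 0 ?
        (double)best_aln.matches / (double)best_aln.alen : 0.0;
      bool pass =
        (double)alen >= min_aligned_frac * (double)L - 1e-9 &&
        ident >= min_identity - 1e-9 &&
        best_score > second_score &&                    // ties never unique
        (double)(best_score - (second_score <= SCORE_NONE ?
                               -2 * L : second_score)) >= (double)margin;
      if (pass) { fam = best_ref + 1; strd = best_aln.strand; }
      else { alen = 0; }
    }
    family[q] = fam;
    aligned[q] = alen;
    score[q] = (best_score <= SCORE_NONE) ? NA_INTEGER : best_score;
    second[q] = (second_score <= SCORE_NONE) ? NA_INTEGER : second_score;
    identity[q] = ident;
    strand[q] = strd;
  }
  return List::create(_["family"] = family, _["aligned_bp"] = aligned,
                      _["score"] = score, _["second_score"] = second,
                      _["identity"] = identity, _["strand"] = strand);
}

// Maximum ungapped diagonal identity between two sequences (both strands),
// considering only diagonals with at least `min_overlap` aligned bases.
// Used to keep TE reference libraries mutually divergent.
// [[Rcpp::export]]
double cpp_pair_identity(std::string a, std::string b, int min_overlap) {
  std::vector<int> va = encode(a);
  std::vector<int> vb = encode(b);
  double best = 0.0;
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int>& q = (strand == 0) ? va : revcomp(va);
    const int L = (int)q.size(), n = (int)vb.size();
    for (int diag = -(L - 1); diag < n; ++diag) {
      int i0 = std::max(0, -diag), i1 = std::min(L, n - diag);
      int alen = i1 - i0;
      if (alen < min_overlap) continue;
      int matches = 0;
      for (int i = i0; i < i1; ++i)
        if (q[i] >= 0 && q[i] == vb[i + diag]) ++matches;
      double ident = (double)matches / (double)alen;
      if (ident > best) best = ident;
    }
  }
  return best;
}
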