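#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exact-seed, ungapped-extension short-read mapper.
// A read maps at reference position p (0-based, on either strand) iff
//  (i) some seed_k-mer of the read matches the reference exactly at the
//      corresponding offset, and
// (ii) the full-length ungapped comparison at p has <= max_mismatches
//      mismatches ('N' always counts as a mismatch).
// Positions must fit the whole read: 0 <= p <= L - read_len.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char revcomp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 'T'; case 'c': return 'G';
    case 'g': return 'C'; case 't': return 'A';
    default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void index_kmers(const std::string &ref, int k, KmerIndex &idx) {
  const int L = (int)ref.size();
  if (L < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < L; ++i) {
    int b = base2bit(ref[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx[h].push_back(i - k + 1);
  }
}

static int count_mismatches(const std::string &ref, const std::string &read,
                            int pos, int cap) {
  int mm = 0;
  const int n = (int)read.size();
  for (int i = 0; i < n; ++i) {
    char r = ref[pos + i], q = read[i];
    int br = base2bit(r), bq = base2bit(q);
    if (br < 0 || bq < 0 || br != bq) { if (++mm > cap) return mm; }
  }
  return mm;
}

struct Hit { int read; int pos; char strand; int mism; };

static void candidates_for(const std::string &ref, const std::string &read,
                           int k, const KmerIndex &idx, std::vector<int> &cand) {
  cand.clear();
  const int n = (int)read.size();
  const int L = (int)ref.size();
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(read[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = idx.find(h);
      if (it != idx.end()) {
        int off = i - k + 1;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int p = it->second[t] - off;
          if (p >= 0 && p + n <= L) cand.push_back(p);
        }
      }
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(std::string ref, CharacterVector reads,
                   int seed_k, int max_mismatches, bool best_only) {
  if (seed_k < 1) stop("seed_k must be >= 1");
  KmerIndex idx;
  index_kmers(ref, seed_k, idx);
  const int L = (int)ref.size();

  std::vector<Hit> hits;
  std::vector<int> cand;
  std::vector<int> cover(L + 1, 0); // difference array

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int n = (int)fwd.size();
    if (n < seed_k || n > L) continue;
    std::string rev(n, 'N');
    for (int i = 0; i < n; ++i) rev[i] = revcomp_char(fwd[n - 1 - i]);

    std::vector<Hit> rh;
    for (int s = 0; s < 2; ++s) {
      const std::string &q = (s == 0) ? fwd : rev;
      candidates_for(ref, q, seed_k, idx, cand);
      for (size_t c = 0; c < cand.size(); ++c) {
        int mm = count_mismatches(ref, q, cand[c], max_mismatches);
        if (mm <= max_mismatches) {
          Hit h; h.read = r + 1; h.pos = cand[c];
          h.strand = (s == 0) ? '+' : '-'; h.mism = mm;
          rh.push_back(h);
        }
      }
    }
    if (rh.empty()) continue;
    if (best_only) {
      // minimal mismatches, then leftmost position, then forward strand
      size_t bi = 0;
      for (size_t i = 1; i < rh.size(); ++i) {
        const Hit &a = rh[i], &b = rh[bi];
        if (a.mism < b.mism ||
            (a.mism == b.mism && (a.pos < b.pos ||
             (a.pos == b.pos && a.strand == '+' && b.strand == '-'))))
          bi = i;
      }
      Hit h = rh[bi]; rh.clear(); rh.push_back(h);
    }
    for (size_t i = 0; i < rh.size(); ++i) {
      hits.push_back(rh[i]);
      cover[rh[i].pos] += 1;
      cover[rh[i].pos + n] -= 1;
    }
  }

  IntegerVector mask(L);
  int acc = 0;
  for (int i = 0; i < L; ++i) { acc += cover[i]; mask[i] = (acc > 0) ? 1 : 0; }

  const size_t H = hits.size();
  IntegerVector hread(H), hpos(H), hmm(H);
  CharacterVector hstrand(H);
  for (size_t i = 0; i < H; ++i) {
    hread[i] = hits[i].read; hpos[i] = hits[i].pos;
    hmm[i] = hits[i].mism; hstrand[i] = std::string(1, hits[i].strand);
  }
  return List::create(_["mask"] = mask,
                      _["read"] = hread, _["pos"] = hpos,
                      _["strand"] = hstrand, _["mismatches"] = hmm);
}
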