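#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Banded semi-global edit distance with unit costs.
// The query (read) is aligned end-to-end; leading/trailing gaps on the
// reference are free (infix alignment). The band is measured around the
// main diagonal and widened automatically by the length difference, so a
// read that drifts by indels stays inside the band as long as the net
// excursion is below `band`.
// [[Rcpp::export]]
int banded_edit_semiglobal(const std::string& read, const std::string& ref,
                           int band) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  const int INF = 1 << 28; // sentinel; never overflows when incremented
  const int wl = band + std::max(0, m - n);
  const int wr = band + std::max(0, n - m);
  const int W = wl + wr + 1; // band width; index b=1..W <-> j = i - wl - 1 + b
  std::vector<int> prev(W + 2, INF), cur(W + 2, INF);
  // row 0: D[0][j] = 0 for j in [0, min(wr, n)] (free start in reference)
  for (int j = 0; j <= std::min(wr, n); ++j) prev[j + wl + 1] = 0;
  for (int i = 1; i <= m; ++i) {
    const int s = i - wl; // j at band index b=1
    const int jlo = std::max(1, s);
    const int jhi = std::min(n, i + wr);
    const int blo = jlo - s + 1, bhi = jhi - s + 1;
    cur[blo - 1] = (s <= 0) ? i : INF; // D[i][0] = i when j=0 is in band
    cur[bhi + 1] = INF;
    prev[W + 1] = INF;
    const char qc = read[i - 1];
    const int* pv = prev.data();
    int* cu = cur.data();
    int left = cu[blo - 1];
    for (int b = blo, j = jlo; b <= bhi; ++b, ++j) {
      int v = pv[b] + (qc == ref[j - 1] ? 0 : 1); // diagonal
      const int up = pv[b + 1] + 1;
      if (up < v) v = up;
      const int lf = left + 1;
      if (lf < v) v = lf;
      cu[b] = v;
      left = v;
    }
    std::swap(prev, cur);
  }
  // optimum over the last row's band (free end in reference; the band is
  // widened by n - m so j = n is always inside it)
  int best = INF;
  {
    const int s = m - wl;
    const int jlo = std::max(0, s);
    const int jhi = std::min(n, m + wr);
    for (int j = jlo; j <= jhi; ++j) best = std::min(best, prev[j - s + 1]);
  }
  return best;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// k-mer vote for read orientation: (+) forward, (-) reverse complement.
// Counts read k-mers present in the forward vs reverse-complemented
// reference k-mer sets; cheap prefilter so each read is aligned once.
// [[Rcpp::export]]
int kmer_orientation_vote(const std::string& read, const std::string& ref,
                          int k = 12) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> fwd, rev;
  uint64_t kf = 0, kr = 0;
  int run = 0;
  const uint64_t shift = 2 * (k - 1);
  for (size_t i = 0; i < ref.size(); ++i) {
    int c = base_code(ref[i]);
    if (c < 0) { run = 0; kf = kr = 0; continue; }
    kf = ((kf << 2) | (uint64_t)c) & mask;
    kr = (kr >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) { fwd.insert(kf); rev.insert(kr); }
  }
  int vote = 0;
  uint64_t kq = 0;
  run = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int c = base_code(read[i]);
    if (c < 0) { run = 0; kq = 0; continue; }
    kq = ((kq << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      if (fwd.count(kq)) ++vote;
      if (rev.count(kq)) --vote;
    }
  }
  return vote;
}

// [[Rcpp::export]]
std::string revcomp_cpp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break; case 'T': r = 'A'; break;
      case 'C': r = 'G'; break; case 'G': r = 'C'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
  return out;
}

// Sequencing-error process: per base, deletion w.p. p_del, insertion of a
// random base before it w.p. p_ins, substitution to a different base w.p.
// p_sub. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string mutate_sequence(const std::string& seq, double p_sub,
                            double p_ins, double p_del) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    double u = unif_rand();
    if (u < p_del) continue;
    if (u < p_del + p_ins) {
      out.push_back(B[std::min(3, (int)(unif_rand() * 4))]);
    }
    char c = seq[i];
    if (unif_rand() < p_sub) {
      char nc = c;
      while (nc == c) nc = B[std::min(3, (int)(unif_rand() * 4))];
      c = nc;
    }
    out.push_back(c);
  }
  return out;
}
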