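// Core k-mer machinery: 2-bit rolling encoder, canonical counting with
// orientation tallies, and a cross-sample presence/absence accumulator.
// k is capped at 31 so a k-mer packs into one 64-bit word; packing is
// big-endian (first base in the highest bits), which makes numeric order on
// codes identical to lexicographic order on strings.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t rc_code(uint64_t x, int k) {
  // complement then reverse 2-bit groups
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = B[x & 3ULL];
    x >>= 2;
  }
  return s;
}

struct Tally {
  uint64_t fwd = 0; // observed in canonical orientation
  uint64_t rev = 0; // observed as the reverse complement of the canonical form
};

// Count canonical k-mers of one read set into `out`.
static void count_reads(const CharacterVector& reads, int k,
                        std::unordered_map<uint64_t, Tally>& out,
                        uint64_t* n_skipped_n) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int) LENGTH(STRING_ELT(reads, r));
    if (len < k) continue;
    uint64_t code = 0, rcode = 0;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      if (b < 0) {
        if (n_skipped_n && run >= 0) *n_skipped_n += std::min(run + 1, k);
        run = 0; code = 0; rcode = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t) b) & mask;
      rcode = (rcode >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++run >= k) {
        if (code <= rcode) out[code].fwd++;
        else out[rcode].rev++;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame count_kmers_cpp(CharacterVector reads, int k, int min_count) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 1 and 31");
  std::unordered_map<uint64_t, Tally> counts;
  uint64_t skipped = 0;
  count_reads(reads, k, counts, &skipped);
  std::vector<uint64_t> keep;
  keep.reserve(counts.size());
  for (const auto& kv : counts)
    if (kv.second.fwd + kv.second.rev >= (uint64_t) min_count)
      keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  R_xlen_t m = keep.size();
  CharacterVector kmer(m);
  NumericVector count(m), fwd(m), rev(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    const Tally& t = counts[keep[i]];
    kmer[i] = decode_kmer(keep[i], k);
    fwd[i] = (double) t.fwd;
    rev[i] = (double) t.rev;
    count[i] = (double) (t.fwd + t.rev);
  }
  DataFrame df = DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                                   _["fwd"] = fwd, _["rev"] = rev,
                                   _["stringsAsFactors"] = false);
  df.attr("n_skipped_n") = (double) skipped;
  return df;
}

// [[Rcpp::export]]
CharacterVector canonicalize_cpp(CharacterVector kmers, int k) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 1 and 31");
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int) LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer length does not match k");
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("ambiguous base in k-mer: %s", s);
      code = (code << 2) | (uint64_t) b;
    }
    uint64_t rc = rc_code(code, k);
    out[i] = decode_kmer(std::min(code, rc), k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int) LENGTH(STRING_ELT(seqs, i));
    std::string r(len, 'N');
    for (int j = 0; j < len; ++j) {
      char c = s[len - 1 - j];
      switch (c) {
      case 'A': case 'a': r[j] = 'T'; break;
      case 'C': case 'c': r[j] = 'G'; break;
      case 'G': case 'g': r[j] = 'C'; break;
      case 'T': case 't': r[j] = 'A'; break;
      default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cross-sample accumulator: per-sample counting (with the per-sample count
// floor) feeding a global map of canonical k-mer -> carrier sample list plus
// aggregate orientation tallies. MAF / monomorphic filtering happens at
// finalisation so the dense matrix is only built for surviving columns.

struct AccEntry {
  uint64_t fwd = 0, rev = 0;
  std::vector<int> samples;
};

struct KmerAcc {
  int k;
  int min_count;
  std::vector<std::string> sample_ids;
  std::unordered_map<uint64_t, AccEntry> map;
  std::unordered_map<uint64_t, Tally> scratch; // reused per-sample counter
  uint64_t n_skipped_n = 0;
};

// [[Rcpp::export]]
SEXP kacc_new(int k, int min_count) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 1 and 31");
  if (min_count < 1) stop("min_count must be >= 1");
  KmerAcc* acc = new KmerAcc();
  acc->k = k;
  acc->min_count = min_count;
  return XPtr<KmerAcc>(acc, true);
}

// [[Rcpp::export]]
void kacc_add_sample(SEXP acc_ptr, std::string sample_id, CharacterVector reads) {
  XPtr<KmerAcc> acc(acc_ptr);
  for (const auto& s : acc->sample_ids)
    if (s == sample_id) stop("duplicate sample id: %s", sample_id.c_str());
  int idx = (int) acc->sample_ids.size();
  acc->sample_ids.push_back(sample_id);
  std::unordered_map<uint64_t, Tally>& counts = acc->scratch;
  counts.clear();
  if (counts.bucket_count() < (1u << 19)) counts.reserve(1u << 19);
  count_reads(reads, acc->k, counts, &acc->n_skipped_n);
  if (acc->map.bucket_count() < (1u << 19)) acc->map.reserve(1u << 19);
  for (const auto& kv : counts) {
    if (kv.second.fwd + kv.second.rev < (uint64_t) acc->min_count) continue;
    AccEntry& e = acc->map[kv.first];
    e.fwd += kv.second.fwd;
    e.rev += kv.second.rev;
    e.samples.push_back(idx);
  }
}

// [[Rcpp::export]]
List kacc_finalize(SEXP acc_ptr, double maf_min) {
  XPtr<KmerAcc> acc(acc_ptr);
  int n = (int) acc->sample_ids.size();
  if (n < 2) stop("need at least 2 samples");
  std::vector<uint64_t> keep;
  for (const auto& kv : acc->map) {
    int s = (int) kv.second.samples.size();
    double f = (double) s / n;
    if (f <= 0.0 || f >= 1.0) continue;              // monomorphic: untestable
    if (std::min(f, 1.0 - f) < maf_min) continue;    // MAF floor
    keep.push_back(kv.first);
  }
  std::sort(keep.begin(), keep.end());               // lexicographic column order
  int m = (int) keep.size();
  IntegerMatrix presence(n, m);
  CharacterVector canon(m), oriented(m);
  NumericVector freq(m);
  for (int j = 0; j < m; ++j) {
    const AccEntry& e = acc->map[keep[j]];
    for (int s : e.samples) presence(s, j) = 1;
    freq[j] = (double) e.samples.size() / n;
    canon[j] = decode_kmer(keep[j], acc->k);
    uint64_t code = (e.rev > e.fwd) ? rc_code(keep[j], acc->k) : keep[j];
    oriented[j] = decode_kmer(code, acc->k);
  }
  CharacterVector samples(n);
  for (int i = 0; i < n; ++i) samples[i] = acc->sample_ids[i];
  return List::create(_["samples"] = samples, _["canonical"] = canon,
                      _["kmers"] = oriented, _["presence"] = presence,
                      _["freq"] = freq,
                      _["n_total_kmers"] = (double) acc->map.size(),
                      _["n_skipped_n"] = (double) acc->n_skipped_n);
}
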