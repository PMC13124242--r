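#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3; anything else is invalid.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Payload sentinels shared with the R side.
static const int CALL_GAP = -3;
static const int CALL_NOVEL = -2;
static const int CALL_AMBIG = -1;

// strand of the reference occurrence(s) relative to the canonical form
static const int STRAND_FWD = 1;
static const int STRAND_REV = 2;
static const int STRAND_MIXED = 3;

struct Payload {
  int feat;      // feature id, or CALL_AMBIG
  uint8_t strand; // bit0 fwd occurrence seen, bit1 rev seen
};

static inline uint64_t pack_hi_lo(int hi, int lo) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(hi)) << 32) |
         static_cast<uint64_t>(static_cast<uint32_t>(lo));
}

// Enumerate canonical k-mers of annotated windows and accumulate the
// feature map.  window feature resolution (TEL > CEN > ARM precedence,
// ARM majority within the window) happens here from per-base labels.
//
// base_feat: per-base feature id (or -1 when unannotated)
// base_prio: per-base klass priority (3 TEL, 2 CEN, 1 ARM, 0 none)
// [[Rcpp::export(name = ".kmer_db_accumulate")]]
List kmer_db_accumulate(CharacterVector seqs, List base_feat_list,
                        List base_prio_list, int k) {
  std::unordered_map<uint64_t, Payload> map;
  map.reserve(1 << 20);
  const uint64_t shift = 2ULL * (k - 1);

  for (int s = 0; s < seqs.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    IntegerVector base_feat = base_feat_list[s];
    IntegerVector base_prio = base_prio_list[s];
    const R_xlen_t L = base_feat.size();
    if (L < k) continue;

    uint64_t fwd = 0, rev = 0;
    int valid = 0; // run length of consecutive ACGT bases ending here
    for (R_xlen_t i = 0; i < L; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | static_cast<uint64_t>(b)) &
            ((k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL));
      rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
      if (++valid < k) continue;

      const R_xlen_t w = i - k + 1; // window start
      // resolve the window's locus feature from the per-base labels
      int best_prio = 0;
      for (R_xlen_t j = w; j <= i; ++j)
        if (base_prio[j] > best_prio) best_prio = base_prio[j];
      if (best_prio == 0) continue; // unannotated window
      int feat = -1;
      if (best_prio >= 2) { // TEL or CEN: first base of that priority
        for (R_xlen_t j = w; j <= i; ++j)
          if (base_prio[j] == best_prio) { feat = base_feat[j]; break; }
      } else { // ARM: majority feature within the window, ties to lowest id
        std::unordered_map<int, int> cnt;
        for (R_xlen_t j = w; j <= i; ++j)
          if (base_prio[j] == 1) cnt[base_feat[j]]++;
        int best_n = -1;
        for (auto &kv : cnt)
          if (kv.second > best_n || (kv.second == best_n && kv.first < feat)) {
            best_n = kv.second; feat = kv.first;
          }
      }

      const bool is_fwd = fwd <= rev;
      const uint64_t key = is_fwd ? fwd : rev;
      auto it = map.find(key);
      if (it == map.end()) {
        Payload p; p.feat = feat; p.strand = is_fwd ? 1 : 2;
        map.emplace(key, p);
      } else {
        if (it->second.feat != feat) it->second.feat = CALL_AMBIG;
        it->second.strand |= is_fwd ? 1 : 2;
      }
    }
  }

  std::vector<uint64_t> keys;
  keys.reserve(map.size());
  for (auto &kv : map) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  const R_xlen_t n = keys.size();
  IntegerVector key_hi(n), key_lo(n), payload(n), strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    key_hi[i] = static_cast<int>(static_cast<uint32_t>(keys[i] >> 32));
    key_lo[i] = static_cast<int>(static_cast<uint32_t>(keys[i] & 0xffffffffULL));
    const Payload &p = map[keys[i]];
    payload[i] = p.feat;
    strand[i] = (p.strand == 1) ? STRAND_FWD : (p.strand == 2) ? STRAND_REV : STRAND_MIXED;
  }
  return List::create(_["key_hi"] = key_hi, _["key_lo"] = key_lo,
                      _["payload"] = payload, _["strand"] = strand);
}

// Query every k-mer window of `seq` against the sorted key arrays.
// calls[i]: feature id, or CALL_AMBIG / CALL_NOVEL / CALL_GAP.
// orient[i]: for unambiguous feature calls with non-MIXED stored strand,
//   1 if the queried orientation matches the stored reference orientation,
//   0 if it is the opposite; NA otherwise.
// [[Rcpp::export(name = ".kmer_db_query")]]
List kmer_db_query(IntegerVector key_hi, IntegerVector key_lo,
                   IntegerVector payload, IntegerVector strand,
                   std::string seq, int k) {
  const R_xlen_t n = key_hi.size();
  std::vector<uint64_t> keys(n);
  for (R_xlen_t i = 0; i < n; ++i) keys[i] = pack_hi_lo(key_hi[i], key_lo[i]);

  const R_xlen_t L = static_cast<R_xlen_t>(seq.size());
  const R_xlen_t ncall = (L >= k) ? (L - k + 1) : 0;
  IntegerVector calls(ncall), orient(ncall);
  const uint64_t shift = 2ULL * (k - 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (R_xlen_t i = 0; i < L; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; }
    else {
      fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
      rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
      ++valid;
    }
    const R_xlen_t w = i - k + 1;
    if (w < 0) continue;
    if (valid < k) { calls[w] = CALL_GAP; orient[w] = NA_INTEGER; continue; }

    const bool q_fwd = fwd <= rev; // query orientation relative to canonical
    const uint64_t key = q_fwd ? fwd : rev;
    auto it = std::lower_bound(keys.begin(), keys.end(), key);
    if (it == keys.end() || *it != key) {
      calls[w] = CALL_NOVEL; orient[w] = NA_INTEGER; continue;
    }
    const R_xlen_t idx = it - keys.begin();
    calls[w] = payload[idx];
    if (payload[idx] >= 0 && strand[idx] != STRAND_MIXED) {
      const bool stored_fwd = (strand[idx] == STRAND_FWD);
      orient[w] = (q_fwd == stored_fwd) ? 1 : 0;
    } else {
      orient[w] = NA_INTEGER;
    }
  }
  return List::create(_["calls"] = calls, _["orient"] = orient);
}

// Hamming-style scoring of a read against a reference window (used by the
// synthetic read scorer): AS = match * n_match - mismatch * n_mismatch.
// [[Rcpp::export(name = ".score_alignment")]]
int score_alignment(std::string read, std::string ref, int match, int mismatch) {
  const size_t n = std::min(read.size(), ref.size());
  int mm = 0;
  for (size_t i = 0; i < n; ++i) {
    char a = read[i], b = ref[i];
    if (a >= 'a') a -= 32;
    if (b >= 'a') b -= 32;
    if (a != b) ++mm;
  }
  return match * static_cast<int>(n - mm) - mismatch * mm;
}
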