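#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// 64-bit FNV-1a, keyed by prefixing the secret key and a salt byte.
// Non-cryptographic but keyed: without the key the bit positions / tokens
// cannot be reproduced by dictionary attack on raw FNV.
static const uint64_t FNV_OFFSET = 1469598103934665603ULL;
static const uint64_t FNV_PRIME = 1099511628211ULL;

static inline uint64_t fnv1a(const uint8_t *p, size_t n, uint64_t h) {
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)p[i];
    h *= FNV_PRIME;
  }
  return h;
}

static inline uint64_t keyed_hash(const std::string &key, uint8_t salt,
                                  const char *val, size_t n) {
  uint64_t h = FNV_OFFSET;
  h = fnv1a((const uint8_t *)key.data(), key.size(), h);
  h = fnv1a(&salt, 1, h);
  h = fnv1a((const uint8_t *)val, n, h);
  // finalisation (splitmix64 mix) to decorrelate the two salted streams
  h ^= h >> 30;
  h *= 0xbf58476d1ce4e5b9ULL;
  h ^= h >> 27;
  h *= 0x94d049bb133111ebULL;
  h ^= h >> 31;
  return h;
}

// q-grams with optional sentinel padding, set semantics, order of first
// occurrence preserved
static std::vector<std::string> qgram_vec(const std::string &s, int q,
                                          bool pad) {
  std::string t;
  if (pad) {
    t = std::string(q - 1, '_') + s + std::string(q - 1, '_');
  } else {
    t = s;
  }
  std::vector<std::string> out;
  if ((int)t.size() < q) return out;
  std::set<std::string> seen;
  for (size_t i = 0; i + (size_t)q <= t.size(); ++i) {
    std::string g = t.substr(i, q);
    if (seen.insert(g).second) out.push_back(g);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_qgram_sets(CharacterVector values, int q, bool pad) {
  int n = values.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(values[i])) {
      out[i] = CharacterVector(0);
      continue;
    }
    std::string s = as<std::string>(values[i]);
    std::vector<std::string> g = qgram_vec(s, q, pad);
    out[i] = wrap(g);
  }
  return out;
}

// Encode a vector of normalised values into column-wise Bloom filters.
// Returns list(bits = raw matrix [nbytes x n], missing = logical[n]).
// [[Rcpp::export]]
List cpp_bloom_encode(CharacterVector values, int q, bool pad, int length_bits,
                      int num_hashes, std::string key) {
  int n = values.size();
  int nbytes = (length_bits + 7) / 8;
  RawMatrix bits(nbytes, n);
  LogicalVector missing(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(values[i])) {
      missing[i] = true;
      continue;
    }
    std::string s = as<std::string>(values[i]);
    if (s.empty()) {
      missing[i] = true;
      continue;
    }
    std::vector<std::string> grams = qgram_vec(s, q, pad);
    if (grams.empty()) {
      missing[i] = true;
      continue;
    }
    missing[i] = false;
    unsigned char *col = (unsigned char *)&bits(0, i);
    for (size_t g = 0; g < grams.size(); ++g) {
      uint64_t g1 = keyed_hash(key, 1, grams[g].data(), grams[g].size());
      uint64_t g2 = keyed_hash(key, 2, grams[g].data(), grams[g].size());
      for (int h = 0; h < num_hashes; ++h) {
        uint64_t pos = (g1 + (uint64_t)h * g2) % (uint64_t)length_bits;
        col[pos >> 3] |= (unsigned char)(1u << (pos & 7));
      }
    }
  }
  return List::create(_["bits"] = bits, _["missing"] = missing);
}

// Keyed hash tokens as 16-char hex strings; NA / empty -> NA.
// [[Rcpp::export]]
CharacterVector cpp_hash_tokens(CharacterVector values, std::string key) {
  int n = values.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(values[i])) {
      out[i] = NA_STRING;
      continue;
    }
    std::string s = as<std::string>(values[i]);
    if (s.empty()) {
      out[i] = NA_STRING;
      continue;
    }
    uint64_t h = keyed_hash(key, 3, s.data(), s.size());
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

static inline int popcount_bytes(const unsigned char *p, int n) {
  int c = 0;
  for (int i = 0; i < n; ++i) c += __builtin_popcount((unsigned int)p[i]);
  return c;
}

// [[Rcpp::export]]
int cpp_popcount_raw(RawVector x) {
  return popcount_bytes((const unsigned char *)RAW(x), x.size());
}

// [[Rcpp::export]]
IntegerVector cpp_popcount_cols(RawMatrix m) {
  int nb = m.nrow(), n = m.ncol();
  IntegerVector out(n);
  const unsigned char *p = (const unsigned char *)RAW(m);
  for (int i = 0; i < n; ++i) out[i] = popcount_bytes(p + (size_t)i * nb, nb);
  return out;
}

// [[Rcpp::export]]
double cpp_dice_raw(RawVector a, RawVector b) {
  int nb = a.size();
  const unsigned char *pa = (const unsigned char *)RAW(a);
  const unsigned char *pb = (const unsigned char *)RAW(b);
  int ca = popcount_bytes(pa, nb), cb = popcount_bytes(pb, nb);
  if (ca + cb == 0) return NA_REAL;
  int inter = 0;
  for (int i = 0; i < nb; ++i)
    inter += __builtin_popcount((unsigned int)(pa[i] & pb[i]));
  return 2.0 * inter / (double)(ca + cb);
}

// 53-bit hash of each raw column (for grouping identical Bloom filters);
// NA where the encoding is missing.
// [[Rcpp::export]]
NumericVector cpp_column_hash(RawMatrix m, LogicalVector missing) {
  int nb = m.nrow(), n = m.ncol();
  NumericVector out(n);
  const unsigned char *p = (const unsigned char *)RAW(m);
  for (int i = 0; i < n; ++i) {
    if (missing[i]) {
      out[i] = NA_REAL;
      continue;
    }
    uint64_t h = fnv1a(p + (size_t)i * nb, nb, FNV_OFFSET);
    out[i] = (double)(h >> 11);
  }
  return out;
}

// Compare candidate pairs field by field.
//   ia, ib      : 1-based record indices (equal length)
//   bloom_bits  : list of raw matrices, one per Dice field
//   bloom_miss  : list of logical vectors, one per Dice field
//   cutoffs     : Dice agree cutoffs, one per Dice field
//   tokens      : integer matrix [n_records x n_token_fields], NA = missing
//   kind        : per linkage field, 0 = bloom/dice, 1 = token/exact
//   slot        : per linkage field, 1-based index into bloom lists or token
//                 matrix columns
// Returns list(states = int matrix [n_pairs x n_fields] with
// 0 agree / 1 disagree / 2 missing, sims = numeric matrix
// [n_pairs x n_bloom] with NA where missing).
// [[Rcpp::export]]
List cpp_compare_pairs(IntegerVector ia, IntegerVector ib, List bloom_bits,
                       List bloom_miss, NumericVector cutoffs,
                       IntegerMatrix tokens, IntegerVector kind,
                       IntegerVector slot) {
  int np = ia.size();
  int nf = kind.size();
  int nbloom = bloom_bits.size();
  IntegerMatrix states(np, nf);
  NumericMatrix sims(np, nbloom);

  std::vector<const unsigned char *> bptr(nbloom);
  std::vector<int> nbytes(nbloom);
  std::vector<const int *> bmiss(nbloom);
  std::vector<std::vector<int> > pops(nbloom);
  for (int s = 0; s < nbloom; ++s) {
    RawMatrix m = bloom_bits[s];
    bptr[s] = (const unsigned char *)RAW(m);
    nbytes[s] = m.nrow();
    LogicalVector mi = bloom_miss[s];
    bmiss[s] = LOGICAL(mi);
    int nrec = m.ncol();
    pops[s].resize(nrec);
    for (int i = 0; i < nrec; ++i)
      pops[s][i] = popcount_bytes(bptr[s] + (size_t)i * nbytes[s], nbytes[s]);
  }

  for (int p = 0; p < np; ++p) {
    int a = ia[p] - 1, b = ib[p] - 1;
    for (int f = 0; f < nf; ++f) {
      int s = slot[f] - 1;
      if (kind[f] == 0) {
        if (bmiss[s][a] || bmiss[s][b]) {
          states(p, f) = 2;
          sims(p, s) = NA_REAL;
          continue;
        }
        int ca = pops[s][a], cb = pops[s][b];
        if (ca + cb == 0) {  // defensive: cannot occur for non-missing
          states(p, f) = 2;
          sims(p, s) = NA_REAL;
          continue;
        }
        const unsigned char *pa = bptr[s] + (size_t)a * nbytes[s];
        const unsigned char *pb = bptr[s] + (size_t)b * nbytes[s];
        int inter = 0;
        for (int i = 0; i < nbytes[s]; ++i)
          inter += __builtin_popcount((unsigned int)(pa[i] & pb[i]));
        double d = 2.0 * inter / (double)(ca + cb);
        sims(p, s) = d;
        states(p, f) = (d >= cutoffs[s]) ? 0 : 1;
      } else {
        int ta = tokens(a, s), tb = tokens(b, s);
        if (ta == NA_INTEGER || tb == NA_INTEGER) {
          states(p, f) = 2;
        } else {
          states(p, f) = (ta == tb) ? 0 : 1;
        }
      }
    }
  }
  return List::create(_["states"] = states, _["sims"] = sims);
}
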