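#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact integer determinant via residues modulo 31-bit primes + CRT.
//
// Entries of the information matrix are small integers, but determinants of
// the larger settings exceed 2^53, so floating point cannot represent (let
// alone compare) them exactly. Residue arithmetic keeps every product below
// 2^62, safely inside int64.
// ---------------------------------------------------------------------------

static int64_t mulmod(int64_t a, int64_t b, int64_t p) { return (a * b) % p; }

// division-free modular product for reduced operands (a, b in [0, p)):
// the double-precision quotient estimate is off by at most one
static inline int64_t mulmod_fast(int64_t a, int64_t b, int64_t p,
                                  double pinv) {
  int64_t q = (int64_t)((double)a * (double)b * pinv);
  int64_t r = a * b - q * p;
  if (r < 0) r += p;
  else if (r >= p) r -= p;
  return r;
}

static int64_t powmod(int64_t a, int64_t e, int64_t p) {
  int64_t r = 1;
  a %= p;
  while (e > 0) {
    if (e & 1) r = mulmod(r, a, p);
    a = mulmod(a, a, p);
    e >>= 1;
  }
  return r;
}

static int64_t invmod(int64_t a, int64_t p) { return powmod(a, p - 2, p); }

static bool is_prime_small(int64_t n) {
  if (n % 2 == 0) return n == 2;
  for (int64_t d = 3; d * d <= n; d += 2)
    if (n % d == 0) return false;
  return true;
}

// descending primes just below 2^31
static const std::vector<int64_t> &prime_pool(size_t need) {
  static std::vector<int64_t> primes;
  int64_t cand = primes.empty() ? 2147483647LL : primes.back() - 2;
  while (primes.size() < need) {
    if (is_prime_small(cand)) primes.push_back(cand);
    cand -= 2;
  }
  return primes;
}

// determinant of A modulo p by Gaussian elimination; entries of A are
// reduced into [0, p) once up front, after which all arithmetic is
// division-free
static int64_t det_mod(const std::vector<int64_t> &A0, int n, int64_t p) {
  std::vector<int64_t> A(A0.size());
  for (size_t i = 0; i < A0.size(); ++i) A[i] = ((A0[i] % p) + p) % p;
  double pinv = 1.0 / (double)p;
  int64_t det = 1;
  for (int i = 0; i < n; ++i) {
    int piv = -1;
    for (int r = i; r < n; ++r)
      if (A[(size_t)r * n + i] != 0) { piv = r; break; }
    if (piv < 0) return 0;
    if (piv != i) {
      for (int c = i; c < n; ++c)
        std::swap(A[(size_t)i * n + c], A[(size_t)piv * n + c]);
      det = p - det;
    }
    int64_t d = A[(size_t)i * n + i];
    det = mulmod_fast(det, d, p, pinv);
    int64_t dinv = invmod(d, p);
    const int64_t *rowi = &A[(size_t)i * n];
    for (int r = i + 1; r < n; ++r) {
      int64_t *rowr = &A[(size_t)r * n];
      int64_t f = rowr[i];
      if (f == 0) continue;
      f = mulmod_fast(f, dinv, p, pinv);
      for (int c = i; c < n; ++c) {
        int64_t v = rowr[c] + p - mulmod_fast(f, rowi[c], p, pinv);
        rowr[c] = v >= p ? v - p : v;
      }
    }
  }
  return det % p;
}

// little-endian base-1e9 big integer helpers
typedef std::vector<uint64_t> bignum;
static const uint64_t BASE = 1000000000ULL;

static void bn_mul_small(bignum &x, uint64_t m) {
  uint64_t carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    uint64_t v = x[i] * m + carry;
    x[i] = v % BASE;
    carry = v / BASE;
  }
  while (carry) { x.push_back(carry % BASE); carry /= BASE; }
}

static void bn_add_small(bignum &x, uint64_t a) {
  size_t i = 0;
  uint64_t carry = a;
  while (carry) {
    if (i == x.size()) x.push_back(0);
    uint64_t v = x[i] + carry;
    x[i] = v % BASE;
    carry = v / BASE;
    ++i;
  }
}

static int bn_cmp(const bignum &a, const bignum &b) {
  size_t la = a.size(), lb = b.size();
  while (la > 0 && a[la - 1] == 0) --la;
  while (lb > 0 && b[lb - 1] == 0) --lb;
  if (la != lb) return la < lb ? -1 : 1;
  for (size_t i = la; i-- > 0;)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

// a -= b, requires a >= b
static void bn_sub(bignum &a, const bignum &b) {
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t v = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (v < 0) { v += BASE; borrow = 1; } else borrow = 0;
    a[i] = (uint64_t)v;
  }
}

static std::string bn_to_string(const bignum &x) {
  size_t l = x.size();
  while (l > 0 && x[l - 1] == 0) --l;
  if (l == 0) return "0";
  std::string s = std::to_string(x[l - 1]);
  char buf[10];
  for (size_t i = l - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09llu", (unsigned long long)x[i]);
    s += buf;
  }
  return s;
}

// [[Rcpp::export(name = "det_exact_cpp")]]
List det_exact_cpp(NumericMatrix M) {
  int n = M.nrow();
  if (M.ncol() != n) stop("matrix must be square");
  std::vector<int64_t> A((size_t)n * n);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) {
      double v = M(r, c);
      if (std::abs(v - std::round(v)) > 1e-9 || std::abs(v) > 9e15)
        stop("matrix entries must be (moderate) integers");
      A[(size_t)r * n + c] = (int64_t)std::llround(v);
    }
  // Hadamard bound on |det| in bits
  double bits = 0.0;
  for (int r = 0; r < n; ++r) {
    double s = 0.0;
    for (int c = 0; c < n; ++c) {
      double v = (double)A[(size_t)r * n + c];
      s += v * v;
    }
    if (s == 0.0) return List::create(_["value"] = 0.0, _["digits"] = "0");
    bits += 0.5 * std::log2(s);
  }
  size_t k = (size_t)std::ceil((bits + 2.0) / 30.9) + 1;
  const std::vector<int64_t> &primes = prime_pool(k);

  std::vector<int64_t> res(k);
  bool all_zero = true;
  for (size_t i = 0; i < k; ++i) {
    res[i] = det_mod(A, n, primes[i]);
    if (res[i] != 0) all_zero = false;
  }
  if (all_zero) return List::create(_["value"] = 0.0, _["digits"] = "0");

  // Garner's algorithm: mixed-radix digits of the residue system
  std::vector<int64_t> d(k);
  d[0] = res[0];
  for (size_t i = 1; i < k; ++i) {
    int64_t p = primes[i];
    int64_t v = 0, pr = 1;
    for (size_t l = 0; l < i; ++l) {
      v = (v + mulmod(d[l] % p, pr, p)) % p;
      pr = mulmod(pr, primes[l] % p, p);
    }
    d[i] = mulmod(((res[i] - v) % p + p) % p, invmod(pr, p), p);
  }
  // x = d[k-1]; x = x * p[l] + d[l] for l = k-2 .. 0; x lies in [0, P)
  bignum x;
  bn_add_small(x, (uint64_t)d[k - 1]);
  for (size_t l = k - 1; l-- > 0;) {
    bn_mul_small(x, (uint64_t)primes[l]);
    bn_add_small(x, (uint64_t)d[l]);
  }
  // negative determinants appear as P - |det|; the primes cover > 2|det|
  bignum P;
  bn_add_small(P, 1);
  for (size_t l = 0; l < k; ++l) bn_mul_small(P, (uint64_t)primes[l]);
  bignum half = P;
  { // half = floor(P / 2)
    uint64_t rem = 0;
    for (size_t i = half.size(); i-- > 0;) {
      uint64_t cur = rem * BASE + half[i];
      half[i] = cur / 2;
      rem = cur % 2;
    }
  }
  bool negative = bn_cmp(x, half) > 0;
  std::string digits;
  if (negative) {
    bignum y = P;
    bn_sub(y, x);
    digits = "-" + bn_to_string(y);
  } else {
    digits = bn_to_string(x);
  }
  double value = std::stod(digits);
  return List::create(_["value"] = value, _["digits"] = digits);
}

// ---------------------------------------------------------------------------
// Batch filling. Mirrors the R reference engine draw-for-draw on R's global
// RNG stream: rng_int(n) = floor(unif_rand() * n); every tie-break consumes
// exactly one draw; random subsets consume one draw per element taken.
// ---------------------------------------------------------------------------

static int rng_int(int n) {
  double u = unif_rand();
  int v = (int)std::floor(u * n);
  if (v >= n) v = n - 1;
  return v;
}

// uniform s-subset of x via partial Fisher-Yates; returns sorted selection
static std::vector<int> random_subset(std::vector<int> x, int s) {
  int m = (int)x.size();
  for (int i = 0; i < s; ++i) {
    int j = i + rng_int(m - i);
    std::swap(x[i], x[j]);
  }
  x.resize(s);
  std::sort(x.begin(), x.end());
  return x;
}

// [[Rcpp::export(name = "fill_batches_cpp")]]
IntegerMatrix fill_batches_cpp(IntegerVector t_star, IntegerVector b_star,
                               bool sba) {
  int T = t_star.size();
  int B = b_star.size();
  std::vector<int> t(t_star.begin(), t_star.end());
  std::vector<int> L((size_t)T * T, 0);
  IntegerMatrix N(B, T);

  for (int k = 0; k < B; ++k) {
    int cap = b_star[k];
    if (cap == 0) continue;
    int rem = B - k;
    std::vector<int> chosen, cand;
    for (int i = 0; i < T; ++i) {
      if (t[i] <= 0) continue;
      if (t[i] == rem) chosen.push_back(i);
      else cand.push_back(i);
    }
    if ((int)chosen.size() > cap)
      stop("infeasible: %d treatments are forced into batch %d but only %d slots remain",
           (int)chosen.size(), k + 1, cap);
    if (sba) {
      if ((int)chosen.size() < cap) {
        std::vector<int> nz;
        for (int i : cand)
          if (L[(size_t)i * T + i] == 0) nz.push_back(i);
        int room = cap - (int)chosen.size();
        if ((int)nz.size() > room) nz = random_subset(nz, room);
        for (int i : nz) {
          chosen.push_back(i);
          cand.erase(std::find(cand.begin(), cand.end(), i));
        }
      }
      if (chosen.empty() && cap >= 2 && (int)cand.size() >= 2) {
        // pairs enumerated in the same (column-major) order as the R engine
        int m = (int)cand.size();
        int best = INT32_MAX;
        std::vector<std::pair<int, int> > ties;
        for (int b = 1; b < m; ++b)
          for (int a = 0; a < b; ++a) {
            int v = L[(size_t)cand[a] * T + cand[b]];
            if (v < best) { best = v; ties.clear(); }
            if (v == best) ties.push_back(std::make_pair(cand[a], cand[b]));
          }
        std::pair<int, int> pick = ties[rng_int((int)ties.size())];
        chosen.push_back(pick.first);
        chosen.push_back(pick.second);
        cand.erase(std::find(cand.begin(), cand.end(), pick.first));
        cand.erase(std::find(cand.begin(), cand.end(), pick.second));
      }
      while ((int)chosen.size() < cap && !cand.empty()) {
        int j;
        if (chosen.empty()) {
          j = cand[rng_int((int)cand.size())];
        } else {
          long best = INT64_MAX;
          std::vector<int> ties;
          for (int c : cand) {
            long s = 0;
            for (int i : chosen) s += L[(size_t)i * T + c];
            if (s < best) { best = s; ties.clear(); }
            if (s == best) ties.push_back(c);
          }
          j = ties[rng_int((int)ties.size())];
        }
        chosen.push_back(j);
        cand.erase(std::find(cand.begin(), cand.end(), j));
      }
    } else { // rba: forced treatments plus a uniform random fill
      int need = std::min(cap - (int)chosen.size(), (int)cand.size());
      if (need > 0) {
        std::vector<int> extra = (need < (int)cand.size())
          ? random_subset(cand, need) : cand;
        for (int i : extra) chosen.push_back(i);
      }
    }
    for (int i : chosen) {
      N(k, i) = 1;
      --t[i];
      for (int j : chosen) ++L[(size_t)i * T + j];
    }
  }
  return N;
}
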