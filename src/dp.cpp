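// Exact dynamic-programming core for counting non-isomorphic rooted trees
// with self-loops, bucketed by (Maxv, Maxs) of the root's child subtrees.
//
// All counts are exact arbitrary-precision integers: a count table for
// moderate (n, delta) already overflows 64-bit (and far exceeds the 2^53
// exact range of doubles), so values are stored as little-endian vectors of
// base-1e9 limbs and crossed into R as decimal strings.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

namespace {

typedef std::vector<uint64_t> Big; // base-1e9 limbs, little-endian; empty == 0
const uint64_t BASE = 1000000000ULL;

void trim(Big &a) {
  while (!a.empty() && a.back() == 0) a.pop_back();
}

Big big_from_u64(uint64_t v) {
  Big a;
  while (v) { a.push_back(v % BASE); v /= BASE; }
  return a;
}

bool is_zero(const Big &a) { return a.empty(); }

Big big_add(const Big &a, const Big &b) {
  size_t n = std::max(a.size(), b.size());
  Big r;
  r.reserve(n + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry + (i < a.size() ? a[i] : 0) + (i < b.size() ? b[i] : 0);
    r.push_back(s % BASE);
    carry = s / BASE;
  }
  if (carry) r.push_back(carry);
  return r;
}

// Schoolbook product. limb*limb <= (1e9-1)^2 ~ 1e18, plus limb and carry,
// stays below 2^64; no 128-bit arithmetic needed.
Big big_mul(const Big &a, const Big &b) {
  if (is_zero(a) || is_zero(b)) return Big();
  Big r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t cur = r[i + j] + a[i] * b[j] + carry;
      r[i + j] = cur % BASE;
      carry = cur / BASE;
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t cur = r[k] + carry;
      r[k] = cur % BASE;
      carry = cur / BASE;
      ++k;
    }
  }
  trim(r);
  return r;
}

// Exact division by a small positive integer; `exact` reports a zero
// remainder.  Divisors here are loop counters q <= n, far below the limb
// base, so rem * BASE never overflows.
Big big_divexact_u64(const Big &a, uint64_t d, bool &exact) {
  Big r(a.size(), 0);
  uint64_t rem = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = rem * BASE + a[i];
    r[i] = cur / d;
    rem = cur % d;
  }
  exact = (rem == 0);
  trim(r);
  return r;
}

int big_cmp(const Big &a, const Big &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

std::string big_to_string(const Big &a) {
  if (is_zero(a)) return "0";
  char buf[16];
  std::string s;
  snprintf(buf, sizeof(buf), "%llu", (unsigned long long)a.back());
  s += buf;
  for (size_t i = a.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09llu", (unsigned long long)a[i]);
    s += buf;
  }
  return s;
}

Big big_from_string(const std::string &s) {
  if (s.empty()) Rcpp::stop("empty big-integer string");
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9')
      Rcpp::stop("big-integer string must contain only decimal digits: '%s'", s);
  }
  Big a;
  size_t end = s.size();
  while (end > 0) {
    size_t start = end >= 9 ? end - 9 : 0;
    uint64_t limb = 0;
    for (size_t i = start; i < end; ++i) limb = limb * 10 + (uint64_t)(s[i] - '0');
    a.push_back(limb);
    end = start;
  }
  trim(a);
  return a;
}

// Multiset coefficient C(h + t - 1, t): number of multisets of size t drawn
// from a family of h distinct members.  Computed as the running product
// prod_{q=1..t} (h + q - 1)/q, each division exact by construction.
Big multiset_big(const Big &h, uint64_t t) {
  if (t == 0) return big_from_u64(1);
  if (is_zero(h)) return Big();
  Big c = big_from_u64(1);
  for (uint64_t q = 1; q <= t; ++q) {
    Big f = big_add(h, big_from_u64(q - 1));
    c = big_mul(c, f);
    bool exact = false;
    c = big_divexact_u64(c, q, exact);
    if (!exact) Rcpp::stop("internal error: multiset coefficient division not exact");
  }
  return c;
}

// ---------------------------------------------------------------------------
// The count table: three families indexed (i, j, k, p) with 1 <= i <= n,
// 0 <= j <= delta, 0 <= k <= n-1, 0 <= p <= delta.
//   ll = h(i, j, k<=, p<=)   trees with Maxv <= k and Maxs <= p
//   el = h(i, j, k=,  p<=)   Maxv == k, Maxs <= p
//   ee = h(i, j, k=,  p=)    Maxv == k, Maxs == p
// Cells with p > j or k > i-1 are never read directly: lookups clamp or
// return zero according to the family semantics.
// ---------------------------------------------------------------------------

struct CountTable {
  int n, D;
  std::vector<Big> ll, el, ee;
  CountTable(int n_, int D_) : n(n_), D(D_) {
    size_t cells = (size_t)n * (D + 1) * n * (D + 1);
    ll.resize(cells);
    el.resize(cells);
    ee.resize(cells);
  }
  size_t idx(int i, int j, int k, int p) const {
    return (((size_t)(i - 1) * (D + 1) + j) * n + k) * (D + 1) + p;
  }
};

const Big kZero; // shared zero for out-of-family lookups

// h(i,j,k<=,p<=): clamp k to i-1 (Maxv <= i-1 always) and p to j.
const Big &get_ll(const CountTable &T, int i, int j, int k, int p) {
  if (k < 0 || p < 0) return kZero;
  if (k > i - 1) k = i - 1;
  if (p > j) p = j;
  return T.ll[T.idx(i, j, k, p)];
}

// h(i,j,k=,p<=): empty when k exceeds i-1; p clamps to j.
const Big &get_el(const CountTable &T, int i, int j, int k, int p) {
  if (k < 0 || p < 0) return kZero;
  if (k > i - 1) return kZero;
  if (p > j) p = j;
  return T.el[T.idx(i, j, k, p)];
}

// h(i,j,k=,p=): empty when k exceeds i-1 or p exceeds j.
const Big &get_ee(const CountTable &T, int i, int j, int k, int p) {
  if (k < 0 || p < 0) return kZero;
  if (k > i - 1 || p > j) return kZero;
  return T.ee[T.idx(i, j, k, p)];
}

void fill_table(CountTable &T, bool cross_check) {
  const int n = T.n, D = T.D;
  const Big one = big_from_u64(1);

  // Boundary layer i = 1: the single vertex carries all j loops, Maxv = 0,
  // Maxs = 0.  h(1,j,0=,0=) = 1; the p= family is empty for p >= 1.
  for (int j = 0; j <= D; ++j) {
    for (int p = 0; p <= j; ++p) {
      T.ll[T.idx(1, j, 0, p)] = one;
      T.el[T.idx(1, j, 0, p)] = one;
      if (p == 0) T.ee[T.idx(1, j, 0, 0)] = one;
    }
  }
  // Boundary layer i = 2: the unique 2-vertex tree has Maxv = 1 and
  // Maxs = s(child); exactly one tree per child-loop count, so
  // h(2,j,1=,p=) = 1 and h(2,j,1=,p<=) = h(2,j,1<=,p<=) = p + 1.
  if (n >= 2) {
    for (int j = 0; j <= D; ++j) {
      for (int p = 0; p <= j; ++p) {
        T.ee[T.idx(2, j, 1, p)] = one;
        T.el[T.idx(2, j, 1, p)] = big_from_u64((uint64_t)p + 1);
        T.ll[T.idx(2, j, 1, p)] = big_from_u64((uint64_t)p + 1);
      }
    }
  }

  // Main sweep, i ascending so every reference lands on a finished layer.
  for (int i = 3; i <= n; ++i) {
    for (int j = 0; j <= D; ++j) {
      for (int k = 1; k <= i - 1; ++k) {
        for (int p = 0; p <= j; ++p) {
          if (k == 1 && p == 0) {
            // Star boundary: all n-1 child subtrees are loopless singletons.
            T.ee[T.idx(i, j, 1, 0)] = one;
            T.el[T.idx(i, j, 1, 0)] = one;
            T.ll[T.idx(i, j, 1, 0)] = one; // 0 (k=0 layer) + 1
            continue;
          }
          // Residual-tree recurrence: q maximal child subtrees drawn (with
          // repetition) from the family H(k,p,k-1<=,p<=), times the count of
          // residual trees left at the root.
          Big c = one;  // running multiset coefficient c(k,p;q)
          Big acc;      // h(i,j,k=,p=) accumulator
          int lmax = (i - 1) / k;
          if (p >= 1) lmax = std::min(lmax, j / p);
          const Big &fam = get_ll(T, k, p, k - 1, p);
          for (int q = 1; q <= lmax; ++q) {
            Big f = big_add(fam, big_from_u64((uint64_t)q - 1));
            c = big_mul(c, f);
            bool exact = false;
            c = big_divexact_u64(c, (uint64_t)q, exact);
            if (!exact)
              Rcpp::stop("exactness assertion failed in incremental multiset update"
                         " at (i=%d, j=%d, k=%d, p=%d, q=%d)", i, j, k, p, q);
            if (cross_check && big_cmp(c, multiset_big(fam, (uint64_t)q)) != 0)
              Rcpp::stop("incremental multiset update disagrees with closed form"
                         " at (i=%d, j=%d, k=%d, p=%d, q=%d)", i, j, k, p, q);
            if (p == 0) {
              const Big &res = get_ll(T, i - q * k, j,
                                      std::min(i - k * q - 1, k - 1), j);
              acc = big_add(acc, big_mul(c, res));
            } else {
              const Big &resA = get_el(T, i - k * q, j - p * q, k,
                                       std::min(j - p * q, p - 1));
              const Big &resB = get_ll(T, i - k * q, j - p * q,
                                       std::min(i - k * q - 1, k - 1), j - p * q);
              acc = big_add(acc, big_mul(c, big_add(resA, resB)));
            }
          }
          T.ee[T.idx(i, j, k, p)] = acc;
          if (p == 0) {
            T.el[T.idx(i, j, k, 0)] = T.ee[T.idx(i, j, k, 0)];
          } else {
            T.el[T.idx(i, j, k, p)] =
                big_add(T.el[T.idx(i, j, k, p - 1)], T.ee[T.idx(i, j, k, p)]);
          }
          T.ll[T.idx(i, j, k, p)] =
              big_add(T.ll[T.idx(i, j, k - 1, p)], T.el[T.idx(i, j, k, p)]);
        }
      }
    }
  }
}

CountTable *table_from_sexp(SEXP ptr) {
  Rcpp::XPtr<CountTable> xp(ptr);
  if (!xp) Rcpp::stop("corrupted count table: null external pointer");
  return xp.get();
}

const Big &lookup_family(const CountTable &T, int i, int j, int k, int p,
                         const std::string &family) {
  if (i < 1 || i > T.n) Rcpp::stop("vertex count %d outside table range 1..%d", i, T.n);
  if (j < 0 || j > T.D) Rcpp::stop("self-loop count %d outside table range 0..%d", j, T.D);
  if (family == "le_le") return get_ll(T, i, j, k, p);
  if (family == "eq_le") return get_el(T, i, j, k, p);
  if (family == "eq_eq") return get_ee(T, i, j, k, p);
  Rcpp::stop("unknown count family '%s'", family);
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_build_table(int n, int delta, bool cross_check) {
  if (n < 1) Rcpp::stop("n must be at least 1");
  if (delta < 0) Rcpp::stop("delta must be nonnegative");
  Rcpp::XPtr<CountTable> xp(new CountTable(n, delta), true);
  fill_table(*xp, cross_check);
  return xp;
}

// [[Rcpp::export]]
Rcpp::List cpp_table_dims(SEXP ptr) {
  CountTable *T = table_from_sexp(ptr);
  return Rcpp::List::create(Rcpp::Named("n_max") = T->n,
                            Rcpp::Named("delta_max") = T->D);
}

// [[Rcpp::export]]
std::string cpp_lookup(SEXP ptr, int i, int j, int k, int p, std::string family) {
  CountTable *T = table_from_sexp(ptr);
  return big_to_string(lookup_family(*T, i, j, k, p, family));
}

// Dump every meaningful cell (k <= i-1, p <= j) of one family for
// serialization and exhaustive identity checks.
// [[Rcpp::export]]
Rcpp::List cpp_dump_family(SEXP ptr, std::string family) {
  CountTable *T = table_from_sexp(ptr);
  std::vector<int> vi, vj, vk, vp;
  std::vector<std::string> val;
  for (int i = 1; i <= T->n; ++i)
    for (int j = 0; j <= T->D; ++j)
      for (int k = 0; k <= i - 1; ++k)
        for (int p = 0; p <= j; ++p) {
          vi.push_back(i); vj.push_back(j); vk.push_back(k); vp.push_back(p);
          val.push_back(big_to_string(lookup_family(*T, i, j, k, p, family)));
        }
  return Rcpp::List::create(
      Rcpp::Named("i") = vi, Rcpp::Named("j") = vj, Rcpp::Named("k") = vk,
      Rcpp::Named("p") = vp, Rcpp::Named("value") = val);
}

// [[Rcpp::export]]
std::string cpp_multiset_coefficient(std::string family_size, int t) {
  if (t < 0) Rcpp::stop("t must be nonnegative");
  return big_to_string(multiset_big(big_from_string(family_size), (uint64_t)t));
}

// [[Rcpp::export]]
std::string cpp_big_add(std::string a, std::string b) {
  return big_to_string(big_add(big_from_string(a), big_from_string(b)));
}

// [[Rcpp::export]]
std::string cpp_big_mul(std::string a, std::string b) {
  return big_to_string(big_mul(big_from_string(a), big_from_string(b)));
}

// [[Rcpp::export]]
int cpp_big_cmp(std::string a, std::string b) {
  return big_cmp(big_from_string(a), big_from_string(b));
}
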