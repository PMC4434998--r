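// Order-k finite-context model over the 4-letter DNA alphabet.
// Counts are exact: dense 4^k table for k <= 12, hashed sparse table above
// (4^28 contexts cannot be stored densely). Both representations are
// value-identical; the choice is invisible to callers.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

constexpr int DENSE_MAX_K = 12;

struct FCM {
  int k;
  bool dense;
  uint64_t mask;                                 // (1 << 2k) - 1
  std::vector<uint32_t> dcounts;                 // dense: ctx*4 + sym
  std::unordered_map<uint64_t, uint32_t> scounts; // sparse: key ctx*4 + sym
  std::unordered_map<uint64_t, uint32_t> stotals; // sparse: key ctx
  uint64_t total_events = 0;

  uint32_t count(uint64_t ctx, int sym) const {
    if (dense) return dcounts[(ctx << 2) | (uint64_t)sym];
    auto it = scounts.find((ctx << 2) | (uint64_t)sym);
    return it == scounts.end() ? 0u : it->second;
  }

  uint32_t total(uint64_t ctx) const {
    if (dense) {
      uint64_t b = ctx << 2;
      return dcounts[b] + dcounts[b + 1] + dcounts[b + 2] + dcounts[b + 3];
    }
    auto it = stotals.find(ctx);
    return it == stotals.end() ? 0u : it->second;
  }
};

void check_symbols(const IntegerVector& s) {
  for (R_xlen_t i = 0; i < s.size(); ++i) {
    int v = s[i];
    if (v < 0 || v > 3)
      stop("sequence symbols must be integers in 0..3 (A,C,G,T)");
  }
}

uint64_t context_code(const IntegerVector& ctx) {
  uint64_t code = 0;
  for (R_xlen_t i = 0; i < ctx.size(); ++i) {
    int v = ctx[i];
    if (v < 0 || v > 3) stop("context symbols must be integers in 0..3");
    code = (code << 2) | (uint64_t)v;
  }
  return code;
}

} // namespace

// [[Rcpp::export(name = ".cpp_fcm_train")]]
SEXP cpp_fcm_train(IntegerVector s, int k) {
  if (k < 1 || k > 28) stop("context order k must be an integer in [1,28]");
  check_symbols(s);
  FCM* m = new FCM();
  m->k = k;
  m->mask = (1ULL << (2 * k)) - 1; // 2k <= 56 bits
  m->dense = (k <= DENSE_MAX_K);
  if (m->dense) m->dcounts.assign((size_t)1 << (2 * k + 2), 0u);

  R_xlen_t n = s.size();
  if (n >= k + 1) {
    uint64_t ctx = 0;
    for (R_xlen_t i = 0; i < k; ++i) ctx = ((ctx << 2) | (uint64_t)s[i]) & m->mask;
    for (R_xlen_t i = k; i < n; ++i) {
      int sym = s[i];
      if (m->dense) {
        ++m->dcounts[(ctx << 2) | (uint64_t)sym];
      } else {
        ++m->scounts[(ctx << 2) | (uint64_t)sym];
        ++m->stotals[ctx];
      }
      ++m->total_events;
      ctx = ((ctx << 2) | (uint64_t)sym) & m->mask;
    }
  }
  XPtr<FCM> p(m, true);
  return p;
}

// [[Rcpp::export(name = ".cpp_fcm_total_events")]]
double cpp_fcm_total_events(SEXP ptr) {
  XPtr<FCM> m(ptr);
  return (double)m->total_events;
}

// count and context total for one (context, symbol) query
// [[Rcpp::export(name = ".cpp_fcm_query")]]
NumericVector cpp_fcm_query(SEXP ptr, IntegerVector ctx, int sym) {
  XPtr<FCM> m(ptr);
  if (ctx.size() != m->k) stop("context must have exactly k symbols");
  if (sym < 0 || sym > 3) stop("symbol must be in 0..3");
  uint64_t code = context_code(ctx);
  return NumericVector::create((double)m->count(code, sym),
                               (double)m->total(code));
}

// per-position code length (bits) of a target under the model
// [[Rcpp::export(name = ".cpp_fcm_profile")]]
NumericVector cpp_fcm_profile(SEXP ptr, IntegerVector x, double alpha) {
  XPtr<FCM> m(ptr);
  if (alpha <= 0) stop("alpha must be positive");
  check_symbols(x);
  R_xlen_t n = x.size();
  int k = m->k;
  NumericVector out(n);
  const double l2 = std::log(2.0);
  R_xlen_t head = std::min((R_xlen_t)k, n);
  for (R_xlen_t i = 0; i < head; ++i) out[i] = 2.0; // no full context
  if (n <= k) return out;
  uint64_t ctx = 0;
  for (R_xlen_t i = 0; i < k; ++i) ctx = ((ctx << 2) | (uint64_t)x[i]) & m->mask;
  for (R_xlen_t i = k; i < n; ++i) {
    int sym = x[i];
    double c = (double)m->count(ctx, sym);
    double t = (double)m->total(ctx);
    double p = (c + alpha) / (t + 4.0 * alpha);
    out[i] = -std::log(p) / l2;
    ctx = ((ctx << 2) | (uint64_t)sym) & m->mask;
  }
  return out;
}

// all nonzero (context, symbol) counts, sorted by context code then symbol;
// intended for small k (tests, inspection)
// [[Rcpp::export(name = ".cpp_fcm_counts")]]
DataFrame cpp_fcm_counts(SEXP ptr) {
  XPtr<FCM> m(ptr);
  std::vector<uint64_t> keys;
  if (m->dense) {
    for (uint64_t key = 0; key < m->dcounts.size(); ++key)
      if (m->dcounts[key] > 0) keys.push_back(key);
  } else {
    keys.reserve(m->scounts.size());
    for (auto& kv : m->scounts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
  }
  R_xlen_t nr = (R_xlen_t)keys.size();
  NumericVector ctx_code(nr);
  IntegerVector sym(nr), cnt(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    uint64_t key = keys[i];
    ctx_code[i] = (double)(key >> 2);
    sym[i] = (int)(key & 3);
    cnt[i] = (int)m->count(key >> 2, (int)(key & 3));
  }
  return DataFrame::create(_["context_code"] = ctx_code,
                           _["symbol_code"] = sym,
                           _["count"] = cnt);
}
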