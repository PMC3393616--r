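#ifndef SETDESIGN_INTERVAL_H
#define SETDESIGN_INTERVAL_H

#include <cmath>
#include <limits>
#include <algorithm>

// Scalar interval with outward rounding realised by nudging every computed
// endpoint one unit in the last place outward.  This keeps the containment
// guarantee without touching the global FPU rounding mode.

namespace sd {

static const double INF = std::numeric_limits<double>::infinity();

struct Ivl {
  double lo, hi;
};

inline Ivl ivl(double lo, double hi) { return Ivl{lo, hi}; }
inline Ivl ipoint(double x) { return Ivl{x, x}; }
inline Ivl iwhole() { return Ivl{-INF, INF}; }

inline bool ifinite(const Ivl &a) {
  return std::isfinite(a.lo) && std::isfinite(a.hi);
}
inline bool ivalid(const Ivl &a) { return a.lo <= a.hi; }  // false on NaN

inline double pdn(double x) {
  if (std::isnan(x)) return -INF;
  if (x == -INF) return x;
  return std::nextafter(x, -INF);
}
inline double pup(double x) {
  if (std::isnan(x)) return INF;
  if (x == INF) return x;
  return std::nextafter(x, INF);
}

inline Ivl iadd(const Ivl &a, const Ivl &b) {
  return Ivl{pdn(a.lo + b.lo), pup(a.hi + b.hi)};
}
inline Ivl isub(const Ivl &a, const Ivl &b) {
  return Ivl{pdn(a.lo - b.hi), pup(a.hi - b.lo)};
}
inline Ivl ineg(const Ivl &a) { return Ivl{-a.hi, -a.lo}; }

// 0 * (+/-Inf) must be 0 for set products (0 times anything is 0).
inline double m0(double x, double y) {
  if (x == 0.0 || y == 0.0) return 0.0;
  return x * y;
}

inline Ivl imul(const Ivl &a, const Ivl &b) {
  double p1 = m0(a.lo, b.lo), p2 = m0(a.lo, b.hi);
  double p3 = m0(a.hi, b.lo), p4 = m0(a.hi, b.hi);
  double lo = std::fmin(std::fmin(p1, p2), std::fmin(p3, p4));
  double hi = std::fmax(std::fmax(p1, p2), std::fmax(p3, p4));
  if (std::isnan(p1) || std::isnan(p2) || std::isnan(p3) || std::isnan(p4))
    return iwhole();
  return Ivl{pdn(lo), pup(hi)};
}

// Division; *ok set to false when 0 is in the divisor.
inline Ivl idiv(const Ivl &a, const Ivl &b, bool *ok) {
  if (b.lo <= 0.0 && b.hi >= 0.0) {
    *ok = false;
    return iwhole();
  }
  double p1 = a.lo / b.lo, p2 = a.lo / b.hi, p3 = a.hi / b.lo, p4 = a.hi / b.hi;
  double lo = std::fmin(std::fmin(p1, p2), std::fmin(p3, p4));
  double hi = std::fmax(std::fmax(p1, p2), std::fmax(p3, p4));
  if (std::isnan(p1) || std::isnan(p2) || std::isnan(p3) || std::isnan(p4))
    return iwhole();
  return Ivl{pdn(lo), pup(hi)};
}

inline Ivl iscale(const Ivl &a, double s) { return imul(a, ipoint(s)); }

inline Ivl ihull(const Ivl &a, const Ivl &b) {
  return Ivl{std::fmin(a.lo, b.lo), std::fmax(a.hi, b.hi)};
}
inline bool isubset(const Ivl &a, const Ivl &b) {  // a subset of b
  return a.lo >= b.lo && a.hi <= b.hi;
}
inline bool idisjoint(const Ivl &a, const Ivl &b) {
  return a.hi < b.lo || a.lo > b.hi;
}
inline double iwidth(const Ivl &a) { return a.hi - a.lo; }
inline double imid(const Ivl &a) {
  double m = 0.5 * (a.lo + a.hi);
  if (!std::isfinite(m)) m = a.lo + 0.5 * (a.hi - a.lo);
  return m;
}

}  // namespace sd

#endif
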