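// Validated integration and set-inversion core.
//
// The ODE right-hand side arrives as a "tape": a topologically ordered list
// of elementary instructions (+, -, *, /, neg) over registers.  Registers
// 0..(n_in-1) hold the inputs (states, then parameters); constant literals
// are preloaded into dedicated registers.  Taylor coefficients of the ODE
// solution are generated by running the tape order by order with the
// classical convolution recurrences, optionally carrying first derivatives
// with respect to the inputs (forward mode over the Taylor recurrences).
//
// Each integration step is a parametric mean-value (EMV) form.  The
// enclosure is maintained as
//
//     x(t)  in  xm(t) + C(t) * dp + A(t) * r(t)
//
// with xm the point trajectory of the box midpoint, dp the fixed centred
// parameter deviation box, C a point matrix tracking the solution's
// sensitivity to the parameters (so the dominant parameter dependence is a
// point-matrix * fixed-interval product that does not compound), A a
// QR-orthonormal preconditioning frame and r the interval deviation that
// absorbs remainders and Jacobian widths.  Steps that cannot be validated
// at the grid step size are retried at halved sub-steps.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include "interval.h"

using namespace Rcpp;
using sd::Ivl;
using sd::INF;

// ---------------------------------------------------------------------------
// Tape

enum OpCode { OP_ADD = 1, OP_SUB = 2, OP_MUL = 3, OP_DIV = 4, OP_NEG = 5 };

struct Tape {
  int n_reg, n_in, n_state;
  std::vector<int> op, ia, ib, iout;         // instructions
  std::vector<int> cslot;                    // constant registers
  std::vector<double> cval;
  std::vector<int> out_slot;                 // rhs register per state
};

static Tape tape_from_list(const List &tl) {
  Tape t;
  t.n_reg = as<int>(tl["n_reg"]);
  t.n_in = as<int>(tl["n_in"]);
  IntegerVector op = tl["op"], ia = tl["arg1"], ib = tl["arg2"], io = tl["out"];
  t.op.assign(op.begin(), op.end());
  t.ia.assign(ia.begin(), ia.end());
  t.ib.assign(ib.begin(), ib.end());
  t.iout.assign(io.begin(), io.end());
  IntegerVector cs = tl["const_slot"];
  NumericVector cv = tl["const_val"];
  t.cslot.assign(cs.begin(), cs.end());
  t.cval.assign(cv.begin(), cv.end());
  IntegerVector os = tl["out_slot"];
  t.out_slot.assign(os.begin(), os.end());
  t.n_state = (int)t.out_slot.size();
  return t;
}

// ---------------------------------------------------------------------------
// Taylor coefficient generation on the tape

struct TaylorEval {
  const Tape &tp;
  int K, d;        // max order, gradient dimension (= n_in) if with_grad
  bool with_grad;
  bool ok;         // false on division by an interval containing zero
  std::vector<Ivl> val;  // n_reg * (K+1)
  std::vector<Ivl> grd;  // n_reg * (K+1) * d

  TaylorEval(const Tape &tp_, int K_, bool grad_)
      : tp(tp_), K(K_), d(tp_.n_in), with_grad(grad_), ok(true) {
    val.assign((size_t)tp.n_reg * (K + 1), Ivl{0.0, 0.0});
    if (with_grad) grd.assign((size_t)tp.n_reg * (K + 1) * d, Ivl{0.0, 0.0});
  }
  inline Ivl &V(int r, int j) { return val[(size_t)r * (K + 1) + j]; }
  inline Ivl &G(int r, int j, int m) {
    return grd[((size_t)r * (K + 1) + j) * d + m];
  }

  void instr_order(int idx, int j) {
    int o = tp.op[idx], a = tp.ia[idx], b = tp.ib[idx], w = tp.iout[idx];
    switch (o) {
      case OP_ADD:
        V(w, j) = sd::iadd(V(a, j), V(b, j));
        if (with_grad)
          for (int m = 0; m < d; ++m)
            G(w, j, m) = sd::iadd(G(a, j, m), G(b, j, m));
        break;
      case OP_SUB:
        V(w, j) = sd::isub(V(a, j), V(b, j));
        if (with_grad)
          for (int m = 0; m < d; ++m)
            G(w, j, m) = sd::isub(G(a, j, m), G(b, j, m));
        break;
      case OP_NEG:
        V(w, j) = sd::ineg(V(a, j));
        if (with_grad)
          for (int m = 0; m < d; ++m) G(w, j, m) = sd::ineg(G(a, j, m));
        break;
      case OP_MUL: {
        Ivl acc{0.0, 0.0};
        for (int i = 0; i <= j; ++i)
          acc = sd::iadd(acc, sd::imul(V(a, i), V(b, j - i)));
        V(w, j) = acc;
        if (with_grad) {
          for (int m = 0; m < d; ++m) {
            Ivl g{0.0, 0.0};
            for (int i = 0; i <= j; ++i) {
              g = sd::iadd(g, sd::imul(G(a, i, m), V(b, j - i)));
              g = sd::iadd(g, sd::imul(V(a, i), G(b, j - i, m)));
            }
            G(w, j, m) = g;
          }
        }
        break;
      }
      case OP_DIV: {
        Ivl num = V(a, j);
        for (int i = 1; i <= j; ++i)
          num = sd::isub(num, sd::imul(V(b, i), V(w, j - i)));
        bool dok = true;
        V(w, j) = sd::idiv(num, V(b, 0), &dok);
        if (!dok) ok = false;
        if (with_grad) {
          for (int m = 0; m < d; ++m) {
            Ivl gn = G(a, j, m);
            for (int i = 1; i <= j; ++i) {
              gn = sd::isub(gn, sd::imul(G(b, i, m), V(w, j - i)));
              gn = sd::isub(gn, sd::imul(V(b, i), G(w, j - i, m)));
            }
            bool d2 = true, d3 = true;
            Ivl t1 = sd::idiv(gn, V(b, 0), &d2);
            Ivl t2 = sd::imul(V(w, j), sd::idiv(G(b, 0, m), V(b, 0), &d3));
            if (!d2 || !d3) ok = false;
            G(w, j, m) = sd::isub(t1, t2);
          }
        }
        break;
      }
      default:
        ok = false;
    }
  }

  // Generate solution Taylor coefficients of the ODE over the input box X
  // (length n_in: states then parameters; parameters have zero dynamics).
  // Afterwards V(i, j) is the j-th solution coefficient of component i.
  void run(const std::vector<Ivl> &X) {
    int n = tp.n_state;
    for (size_t c = 0; c < tp.cslot.size(); ++c)
      V(tp.cslot[c], 0) = sd::ipoint(tp.cval[c]);
    for (int j = 0; j <= K; ++j) {
      for (int i = 0; i < tp.n_in; ++i) {
        if (j == 0) {
          V(i, 0) = X[i];
          if (with_grad)
            for (int m = 0; m < d; ++m)
              G(i, 0, m) = (m == i) ? sd::ipoint(1.0) : sd::ipoint(0.0);
        } else if (i < n) {
          bool dok = true;
          V(i, j) = sd::idiv(V(tp.out_slot[i], j - 1), sd::ipoint((double)j),
                             &dok);
          if (with_grad)
            for (int m = 0; m < d; ++m)
              G(i, j, m) = sd::idiv(G(tp.out_slot[i], j - 1, m),
                                    sd::ipoint((double)j), &dok);
          if (!dok) ok = false;
        }
        // parameter components: coefficients beyond order 0 stay exactly 0
      }
      for (size_t idx = 0; idx < tp.op.size(); ++idx) instr_order((int)idx, j);
      if (!ok) return;
    }
  }
};

// Plain interval evaluation of the rhs f(X) over an input box
// (length n_in); returns the n_state rhs components.
static bool eval_rhs(const Tape &tp, const std::vector<Ivl> &X,
                     std::vector<Ivl> &F) {
  TaylorEval te(tp, 0, false);
  te.run(X);
  F.assign(tp.n_state, Ivl{0.0, 0.0});
  for (int i = 0; i < tp.n_state; ++i) F[i] = te.V(tp.out_slot[i], 0);
  return te.ok;
}

// ---------------------------------------------------------------------------
// Small dense linear algebra (point matrices row-major)

static bool householder_qr_q(const std::vector<double> &Min, int d,
                             std::vector<double> &Q) {
  std::vector<double> R(Min);
  for (double x : R)
    if (!std::isfinite(x)) return false;
  Q.assign((size_t)d * d, 0.0);
  for (int i = 0; i < d; ++i) Q[(size_t)i * d + i] = 1.0;
  std::vector<double> v(d);
  for (int k = 0; k < d; ++k) {
    double nrm = 0.0;
    for (int i = k; i < d; ++i) nrm += R[(size_t)i * d + k] * R[(size_t)i * d + k];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-300) continue;
    double a = R[(size_t)k * d + k];
    double alpha = (a >= 0.0) ? -nrm : nrm;
    double vnorm2 = 0.0;
    for (int i = k; i < d; ++i) {
      v[i] = R[(size_t)i * d + k];
      if (i == k) v[i] -= alpha;
      vnorm2 += v[i] * v[i];
    }
    if (vnorm2 < 1e-300) continue;
    for (int j = k; j < d; ++j) {  // R <- (I - 2vv'/v'v) R
      double s = 0.0;
      for (int i = k; i < d; ++i) s += v[i] * R[(size_t)i * d + j];
      s *= 2.0 / vnorm2;
      for (int i = k; i < d; ++i) R[(size_t)i * d + j] -= s * v[i];
    }
    for (int j = 0; j < d; ++j) {  // Q <- Q (I - 2vv'/v'v)
      double s = 0.0;
      for (int i = k; i < d; ++i) s += Q[(size_t)j * d + i] * v[i];
      s *= 2.0 / vnorm2;
      for (int i = k; i < d; ++i) Q[(size_t)j * d + i] -= s * v[i];
    }
  }
  for (double x : Q)
    if (!std::isfinite(x)) return false;
  return true;
}

// Solve A X = B rigorously where A is a point matrix (treated as degenerate
// intervals) and B an interval matrix with ncol columns; interval Gaussian
// elimination with partial pivoting.  Returns false if a pivot contains 0.
static bool ivl_solve(const std::vector<double> &A, int d,
                      std::vector<Ivl> &B, int ncol) {
  std::vector<Ivl> M((size_t)d * d);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j)
      M[(size_t)i * d + j] = sd::ipoint(A[(size_t)i * d + j]);
  std::vector<int> perm(d);
  for (int i = 0; i < d; ++i) perm[i] = i;
  for (int k = 0; k < d; ++k) {
    int piv = k;
    double best = std::fabs(sd::imid(M[(size_t)perm[k] * d + k]));
    for (int i = k + 1; i < d; ++i) {
      double c = std::fabs(sd::imid(M[(size_t)perm[i] * d + k]));
      if (c > best) { best = c; piv = i; }
    }
    std::swap(perm[k], perm[piv]);
    Ivl pk = M[(size_t)perm[k] * d + k];
    if (pk.lo <= 0.0 && pk.hi >= 0.0) return false;
    for (int i = k + 1; i < d; ++i) {
      bool dok = true;
      Ivl f = sd::idiv(M[(size_t)perm[i] * d + k], pk, &dok);
      if (!dok) return false;
      for (int j = k + 1; j < d; ++j)
        M[(size_t)perm[i] * d + j] =
            sd::isub(M[(size_t)perm[i] * d + j],
                     sd::imul(f, M[(size_t)perm[k] * d + j]));
      for (int c = 0; c < ncol; ++c)
        B[(size_t)perm[i] * ncol + c] =
            sd::isub(B[(size_t)perm[i] * ncol + c],
                     sd::imul(f, B[(size_t)perm[k] * ncol + c]));
    }
  }
  std::vector<Ivl> X((size_t)d * ncol);
  for (int k = d - 1; k >= 0; --k) {
    for (int c = 0; c < ncol; ++c) {
      Ivl s = B[(size_t)perm[k] * ncol + c];
      for (int j = k + 1; j < d; ++j)
        s = sd::isub(s, sd::imul(M[(size_t)perm[k] * d + j],
                                 X[(size_t)j * ncol + c]));
      bool dok = true;
      X[(size_t)k * ncol + c] = sd::idiv(s, M[(size_t)perm[k] * d + k], &dok);
      if (!dok) return false;
    }
  }
  B = X;
  return true;
}

// ---------------------------------------------------------------------------
// Settings

struct Settings {
  double h, alpha, state_cap;
  int K, max_inflate, max_halvings;
  long budget;
  bool certs;
};

static Settings settings_from_list(const List &sl) {
  Settings s;
  s.h = as<double>(sl["h"]);
  s.K = as<int>(sl["k"]);
  s.alpha = as<double>(sl["alpha"]);
  s.max_inflate = as<int>(sl["max_inflate"]);
  s.max_halvings = as<int>(sl["max_halvings"]);
  s.budget = (long)as<double>(sl["substep_budget"]);
  s.state_cap = as<double>(sl["state_cap"]);
  s.certs = as<bool>(sl["certificates"]);
  return s;
}

// ---------------------------------------------------------------------------
// First-order (Picard) a-priori enclosure over one step.
//
// Find B (states) with X + [0,h] F(B, P) inside B; then every solution
// starting in X stays in N = X + [0,h] F(B) over the step.  On a
// containment violation only the violating components are widened (hull
// with the Picard image, deviation from the midpoint then inflated by
// 1 + alpha); widening everything at once makes candidate and requirement
// grow in lockstep for coupled systems and the validation never closes.
static bool a_priori_box(const Tape &tp, const std::vector<Ivl> &X,
                         const std::vector<Ivl> &P, double h,
                         const Settings &st, std::vector<Ivl> &B) {
  int n = tp.n_state, p = tp.n_in - n;
  std::vector<Ivl> XP(tp.n_in);
  for (int i = 0; i < n; ++i) XP[i] = X[i];
  for (int j = 0; j < p; ++j) XP[n + j] = P[j];
  std::vector<Ivl> F;
  if (!eval_rhs(tp, XP, F)) return false;
  Ivl Hh{0.0, h};
  B.resize(n);
  for (int i = 0; i < n; ++i) B[i] = sd::iadd(X[i], sd::imul(Hh, F[i]));
  std::vector<Ivl> N(n);
  for (int attempt = 0; attempt < st.max_inflate; ++attempt) {
    for (int i = 0; i < n; ++i) XP[i] = B[i];
    if (!eval_rhs(tp, XP, F)) return false;
    bool inside = true;
    for (int i = 0; i < n; ++i) {
      N[i] = sd::iadd(X[i], sd::imul(Hh, F[i]));
      if (!sd::ivalid(N[i]) || !sd::ifinite(N[i])) return false;
      if (!sd::isubset(N[i], B[i])) inside = false;
    }
    if (inside) { B = N; return true; }
    for (int i = 0; i < n; ++i) {
      if (sd::isubset(N[i], B[i])) continue;
      Ivl H = sd::ihull(B[i], N[i]);
      double mid = sd::imid(H);
      Ivl dev = sd::isub(H, sd::ipoint(mid));
      B[i] = sd::iadd(sd::ipoint(mid), sd::iscale(dev, 1.0 + st.alpha));
      if (!sd::ivalid(B[i]) || !sd::ifinite(B[i])) return false;
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Parametric EMV stepper

struct Stepper {
  const Tape &tp;
  Settings st;
  int n, p;                    // states, parameters
  long used;                   // substeps consumed
  // representation: x in xm + C dp + A r, parameters fixed in P
  std::vector<double> xm;      // state midpoint (n)
  std::vector<double> C;       // n x p parameter-sensitivity point matrix
  std::vector<double> A;       // n x n frame
  std::vector<Ivl> r;          // deviation in frame coordinates (n)
  std::vector<Ivl> H;          // current state hull (n)
  std::vector<Ivl> P;          // parameter box (p)
  std::vector<Ivl> dp;         // centred parameter deviation (p)
  std::vector<double> pm;      // parameter midpoint (p)

  Stepper(const Tape &tp_, const Settings &st_)
      : tp(tp_), st(st_), n(tp_.n_state), p(tp_.n_in - tp_.n_state),
        used(0) {}

  void init(const std::vector<Ivl> &x0, const std::vector<Ivl> &pbox) {
    xm.resize(n);
    C.assign((size_t)n * p, 0.0);
    A.assign((size_t)n * n, 0.0);
    r.resize(n);
    H = x0;
    P = pbox;
    pm.resize(p);
    dp.resize(p);
    for (int i = 0; i < n; ++i) {
      xm[i] = sd::imid(x0[i]);
      A[(size_t)i * n + i] = 1.0;
      r[i] = sd::isub(x0[i], sd::ipoint(xm[i]));
    }
    for (int j = 0; j < p; ++j) {
      pm[j] = sd::imid(pbox[j]);
      dp[j] = sd::isub(pbox[j], sd::ipoint(pm[j]));
    }
  }

  // single EMV step of size h; state modified only on success
  bool try_step(double h) {
    int K = st.K;
    int d = tp.n_in;
    std::vector<Ivl> B;
    if (!a_priori_box(tp, H, P, h, st, B)) return false;

    // remainder coefficients over (B, P)
    std::vector<Ivl> XP(d);
    for (int i = 0; i < n; ++i) XP[i] = B[i];
    for (int j = 0; j < p; ++j) XP[n + j] = P[j];
    TaylorEval teB(tp, K + 1, false);
    teB.run(XP);
    if (!teB.ok) return false;

    // Jacobian coefficients over the current hull (H, P)
    for (int i = 0; i < n; ++i) XP[i] = H[i];
    TaylorEval teX(tp, K, true);
    teX.run(XP);
    if (!teX.ok) return false;

    // point series at the midpoint (xm, pm)
    for (int i = 0; i < n; ++i) XP[i] = sd::ipoint(xm[i]);
    for (int j = 0; j < p; ++j) XP[n + j] = sd::ipoint(pm[j]);
    TaylorEval tem(tp, K, false);
    tem.run(XP);
    if (!tem.ok) return false;

    // interval powers of h
    std::vector<Ivl> hp(K + 2);
    hp[0] = sd::ipoint(1.0);
    for (int j = 1; j <= K + 1; ++j) hp[j] = sd::imul(hp[j - 1], sd::ipoint(h));

    // v = T_K(xm, pm) + remainder; Sx (n x n), Sp (n x p)
    std::vector<Ivl> v(n), Sx((size_t)n * n), Sp((size_t)n * p);
    for (int i = 0; i < n; ++i) {
      Ivl acc{0.0, 0.0};
      for (int j = 0; j <= K; ++j)
        acc = sd::iadd(acc, sd::imul(tem.V(i, j), hp[j]));
      acc = sd::iadd(acc, sd::imul(teB.V(i, K + 1), hp[K + 1]));
      v[i] = acc;
      for (int m = 0; m < n; ++m) {
        Ivl g{0.0, 0.0};
        for (int j = 0; j <= K; ++j)
          g = sd::iadd(g, sd::imul(teX.G(i, j, m), hp[j]));
        Sx[(size_t)i * n + m] = g;
      }
      for (int q = 0; q < p; ++q) {
        Ivl g{0.0, 0.0};
        for (int j = 0; j <= K; ++j)
          g = sd::iadd(g, sd::imul(teX.G(i, j, n + q), hp[j]));
        Sp[(size_t)i * p + q] = g;
      }
    }

    // CP = Sx C + Sp (interval n x p); M = Sx A (interval n x n)
    std::vector<Ivl> CP((size_t)n * p), M((size_t)n * n);
    for (int i = 0; i < n; ++i) {
      for (int q = 0; q < p; ++q) {
        Ivl acc = Sp[(size_t)i * p + q];
        for (int k2 = 0; k2 < n; ++k2)
          acc = sd::iadd(acc, sd::iscale(Sx[(size_t)i * n + k2],
                                         C[(size_t)k2 * p + q]));
        CP[(size_t)i * p + q] = acc;
      }
      for (int m = 0; m < n; ++m) {
        Ivl acc{0.0, 0.0};
        for (int k2 = 0; k2 < n; ++k2)
          acc = sd::iadd(acc, sd::iscale(Sx[(size_t)i * n + k2],
                                         A[(size_t)k2 * n + m]));
        M[(size_t)i * n + m] = acc;
      }
    }

    // direct evaluation hull: v + CP dp + M r
    std::vector<Ivl> Hdir(n);
    for (int i = 0; i < n; ++i) {
      Ivl acc = v[i];
      for (int q = 0; q < p; ++q)
        acc = sd::iadd(acc, sd::imul(CP[(size_t)i * p + q], dp[q]));
      for (int m = 0; m < n; ++m)
        acc = sd::iadd(acc, sd::imul(M[(size_t)i * n + m], r[m]));
      Hdir[i] = acc;
      if (!sd::ivalid(acc) || !sd::ifinite(acc) ||
          std::fabs(acc.lo) > st.state_cap || std::fabs(acc.hi) > st.state_cap)
        return false;
    }

    // split CP into point part C2 and residual D
    std::vector<double> C2((size_t)n * p), xm2(n);
    std::vector<Ivl> D((size_t)n * p);
    for (size_t i = 0; i < CP.size(); ++i) {
      C2[i] = sd::imid(CP[i]);
      D[i] = sd::isub(CP[i], sd::ipoint(C2[i]));
    }
    for (int i = 0; i < n; ++i) xm2[i] = sd::imid(v[i]);

    // new frame from QR of mid(M); fall back to identity
    std::vector<double> Mmid((size_t)n * n), Q;
    for (size_t i = 0; i < M.size(); ++i) Mmid[i] = sd::imid(M[i]);
    bool haveQ = householder_qr_q(Mmid, n, Q);

    // solve Q [Y | w] = [M | D dp + (v - xm2)]
    std::vector<Ivl> RHS((size_t)n * (n + 1));
    auto fill_rhs = [&]() {
      for (int i = 0; i < n; ++i) {
        for (int m = 0; m < n; ++m)
          RHS[(size_t)i * (n + 1) + m] = M[(size_t)i * n + m];
        Ivl acc = sd::isub(v[i], sd::ipoint(xm2[i]));
        for (int q = 0; q < p; ++q)
          acc = sd::iadd(acc, sd::imul(D[(size_t)i * p + q], dp[q]));
        RHS[(size_t)i * (n + 1) + n] = acc;
      }
    };
    fill_rhs();
    bool solved = haveQ && ivl_solve(Q, n, RHS, n + 1);
    if (!solved) {  // identity frame is always sound
      Q.assign((size_t)n * n, 0.0);
      for (int i = 0; i < n; ++i) Q[(size_t)i * n + i] = 1.0;
      fill_rhs();
    }
    std::vector<Ivl> r2(n);
    for (int i = 0; i < n; ++i) {
      Ivl acc = RHS[(size_t)i * (n + 1) + n];
      for (int m = 0; m < n; ++m)
        acc = sd::iadd(acc, sd::imul(RHS[(size_t)i * (n + 1) + m], r[m]));
      r2[i] = acc;
      if (!sd::ivalid(r2[i]) || !sd::ifinite(r2[i])) return false;
    }

    // new hull: (xm2 + C2 dp + Q r2) intersect Hdir
    std::vector<Ivl> H2(n);
    for (int i = 0; i < n; ++i) {
      Ivl acc = sd::ipoint(xm2[i]);
      for (int q = 0; q < p; ++q)
        acc = sd::iadd(acc, sd::iscale(dp[q], C2[(size_t)i * p + q]));
      for (int m = 0; m < n; ++m)
        acc = sd::iadd(acc, sd::iscale(r2[m], Q[(size_t)i * n + m]));
      Ivl is{std::fmax(acc.lo, Hdir[i].lo), std::fmin(acc.hi, Hdir[i].hi)};
      H2[i] = sd::ivalid(is) ? is : Hdir[i];
    }

    xm = xm2; C = C2; A = Q; r = r2; H = H2;
    return true;
  }

  // advance by one grid step st.h, recursively halving on failure
  bool advance(double h, int depth) {
    if (used++ > st.budget) return false;
    std::vector<double> sxm = xm, sC = C, sA = A;
    std::vector<Ivl> sr = r, sH = H;
    if (try_step(h)) return true;
    xm = sxm; C = sC; A = sA; r = sr; H = sH;
    if (depth >= st.max_halvings) return false;
    if (!advance(h / 2.0, depth + 1)) return false;
    return advance(h / 2.0, depth + 1);
  }
};

// ---------------------------------------------------------------------------
// Growth-rate certificates
//
// For models in factored kinetic form x_i' = x_i * g_i(x, p) with
// nonnegative invariant states, interval bounds on g_i over the positive
// orthant (states in [0, Inf)) and the current parameter box justify two
// sound early discards during classification:
//   escape:  inf g_i >= 0 and the enclosure lower bound already exceeds a
//            remaining upper measurement bound -> that measurement can never
//            be met (x_i is nondecreasing from here on);
//   decay:   x_i(t') <= hi_i * exp(sup g_i * (t'-t)); if that bound falls
//            below a remaining lower measurement bound the box is out.

struct GrowthBounds {
  std::vector<bool> avail;
  std::vector<double> glo, ghi;
};

static GrowthBounds growth_bounds(const Tape &gt, int n_state,
                                  const std::vector<Ivl> &pbox) {
  GrowthBounds gb;
  gb.avail.assign(n_state, false);
  gb.glo.assign(n_state, -INF);
  gb.ghi.assign(n_state, INF);
  std::vector<Ivl> X(gt.n_in);
  for (int i = 0; i < n_state; ++i) X[i] = sd::ivl(0.0, INF);
  for (size_t j = 0; j < pbox.size(); ++j) X[n_state + j] = pbox[j];
  TaylorEval te(gt, 0, false);
  te.run(X);
  if (!te.ok) return gb;
  for (int i = 0; i < n_state; ++i) {
    Ivl g = te.V(gt.out_slot[i], 0);
    if (sd::ivalid(g)) {
      gb.avail[i] = true;
      gb.glo[i] = g.lo;
      gb.ghi[i] = g.hi;
    }
  }
  return gb;
}

// ---------------------------------------------------------------------------
// Classification of one parameter box against interval measurements

struct MeasData {
  std::vector<int> gi, comp;   // grid index, 0-based component
  std::vector<double> lo, hi;  // sorted by gi
  int last_gi;
};

static MeasData meas_from(const IntegerVector &gi, const IntegerVector &comp,
                          const NumericVector &lo, const NumericVector &hi) {
  MeasData md;
  int n = gi.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return gi[a] < gi[b]; });
  md.last_gi = 0;
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    md.gi.push_back(gi[i]);
    md.comp.push_back(comp[i]);
    md.lo.push_back(lo[i]);
    md.hi.push_back(hi[i]);
    if (gi[i] > md.last_gi) md.last_gi = gi[i];
  }
  return md;
}

enum ClassCode { CL_UNFEASIBLE = 0, CL_FEASIBLE = 1, CL_INDET = 2, CL_FAIL = 3 };

static int classify_box_core(const Tape &tp, const Tape *gt,
                             const std::vector<Ivl> &x0,
                             const std::vector<Ivl> &pbox, const MeasData &md,
                             const Settings &st) {
  GrowthBounds gb;
  bool have_gb = false;
  if (st.certs && gt != nullptr) {
    gb = growth_bounds(*gt, tp.n_state, pbox);
    have_gb = true;
  }

  Stepper sp(tp, st);
  sp.init(x0, pbox);
  bool contained = true;
  size_t next_m = 0;
  int nmeas = (int)md.gi.size();

  for (int node = 0;; ++node) {
    // measurements at this node
    while (next_m < (size_t)nmeas && md.gi[next_m] == node) {
      const Ivl &xc = sp.H[md.comp[next_m]];
      Ivl y{md.lo[next_m], md.hi[next_m]};
      if (sd::idisjoint(xc, y)) return CL_UNFEASIBLE;
      if (!sd::isubset(xc, y)) contained = false;
      ++next_m;
    }
    if (next_m >= (size_t)nmeas || node >= md.last_gi) break;

    // certificates against remaining measurements
    if (have_gb) {
      for (size_t mi = next_m; mi < (size_t)nmeas; ++mi) {
        int c = md.comp[mi];
        if (!gb.avail[c]) continue;
        const Ivl &xc = sp.H[c];
        if (gb.glo[c] >= 0.0 && xc.lo > md.hi[mi]) return CL_UNFEASIBLE;
        if (std::isfinite(gb.ghi[c])) {
          double dt = (md.gi[mi] - node) * st.h;
          double bound =
              sd::pup(xc.hi * sd::pup(std::exp(sd::pup(gb.ghi[c] * dt))));
          if (bound < md.lo[mi]) return CL_UNFEASIBLE;
        }
      }
    }

    if (!sp.advance(st.h, 0)) return CL_FAIL;
  }
  return contained ? CL_FEASIBLE : CL_INDET;
}

// ---------------------------------------------------------------------------
// R interface helpers

static std::vector<Ivl> mat_to_ivls(const NumericMatrix &m) {
  std::vector<Ivl> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = sd::ivl(m(i, 0), m(i, 1));
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_iv_op(double alo, double ahi, double blo, double bhi,
                        int op) {
  Ivl a{alo, ahi}, b{blo, bhi}, r{0.0, 0.0};
  bool ok = true;
  switch (op) {
    case OP_ADD: r = sd::iadd(a, b); break;
    case OP_SUB: r = sd::isub(a, b); break;
    case OP_MUL: r = sd::imul(a, b); break;
    case OP_DIV: r = sd::idiv(a, b, &ok); break;
    default: stop("unknown interval operation");
  }
  if (!ok) stop("divisor contains zero");
  return NumericVector::create(r.lo, r.hi);
}

// [[Rcpp::export]]
List cpp_taylor_coefficients(List tape, NumericMatrix X, int order) {
  Tape tp = tape_from_list(tape);
  std::vector<Ivl> Xv = mat_to_ivls(X);
  if ((int)Xv.size() != tp.n_in) stop("state box has wrong dimension");
  TaylorEval te(tp, order, false);
  te.run(Xv);
  NumericMatrix lo(order + 1, tp.n_in), hi(order + 1, tp.n_in);
  for (int j = 0; j <= order; ++j)
    for (int i = 0; i < tp.n_in; ++i) {
      lo(j, i) = te.V(i, j).lo;
      hi(j, i) = te.V(i, j).hi;
    }
  return List::create(_["ok"] = te.ok, _["lo"] = lo, _["hi"] = hi);
}

// [[Rcpp::export]]
List cpp_a_priori(List tape, NumericMatrix x0, NumericMatrix pbox,
                  List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  std::vector<Ivl> B;
  bool ok = a_priori_box(tp, mat_to_ivls(x0), mat_to_ivls(pbox), st.h, st, B);
  NumericMatrix out(tp.n_state, 2);
  if (ok)
    for (int i = 0; i < tp.n_state; ++i) {
      out(i, 0) = B[i].lo;
      out(i, 1) = B[i].hi;
    }
  return List::create(_["ok"] = ok, _["box"] = out);
}

static List stepper_state_to_list(const Stepper &sp) {
  int n = sp.n, p = sp.p;
  NumericMatrix Am(n, n), Cm(n, p), rm(n, 2), Hm(n, 2), Pm(p, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) Am(i, j) = sp.A[(size_t)i * n + j];
    for (int q = 0; q < p; ++q) Cm(i, q) = sp.C[(size_t)i * p + q];
    rm(i, 0) = sp.r[i].lo; rm(i, 1) = sp.r[i].hi;
    Hm(i, 0) = sp.H[i].lo; Hm(i, 1) = sp.H[i].hi;
  }
  for (int q = 0; q < p; ++q) { Pm(q, 0) = sp.P[q].lo; Pm(q, 1) = sp.P[q].hi; }
  return List::create(_["mid"] = NumericVector(sp.xm.begin(), sp.xm.end()),
                      _["frame"] = Am, _["psens"] = Cm, _["dev"] = rm,
                      _["hull"] = Hm, _["pbox"] = Pm);
}

static void stepper_state_from_list(Stepper &sp, const List &state) {
  NumericVector mid = state["mid"];
  NumericMatrix Am = state["frame"], Cm = state["psens"], rm = state["dev"],
                Hm = state["hull"], Pm = state["pbox"];
  int n = sp.n, p = sp.p;
  sp.init(mat_to_ivls(Hm), mat_to_ivls(Pm));  // sets pm/dp from pbox
  sp.xm.assign(mid.begin(), mid.end());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) sp.A[(size_t)i * n + j] = Am(i, j);
    for (int q = 0; q < p; ++q) sp.C[(size_t)i * p + q] = Cm(i, q);
    sp.r[i] = sd::ivl(rm(i, 0), rm(i, 1));
    sp.H[i] = sd::ivl(Hm(i, 0), Hm(i, 1));
  }
}

// [[Rcpp::export]]
List cpp_emv_init(List tape, NumericMatrix x0, NumericMatrix pbox) {
  Tape tp = tape_from_list(tape);
  Settings st{};
  st.state_cap = INF;
  Stepper sp(tp, st);
  sp.init(mat_to_ivls(x0), mat_to_ivls(pbox));
  return stepper_state_to_list(sp);
}

// [[Rcpp::export]]
List cpp_emv_step(List tape, List state, List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  Stepper sp(tp, st);
  stepper_state_from_list(sp, state);
  bool ok = sp.advance(st.h, 0);
  List out = stepper_state_to_list(sp);
  out["ok"] = ok;
  return out;
}

// [[Rcpp::export]]
List cpp_propagate(List tape, NumericMatrix x0, NumericMatrix pbox, int ngrid,
                   List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  Stepper sp(tp, st);
  sp.init(mat_to_ivls(x0), mat_to_ivls(pbox));
  int n = tp.n_state;
  NumericMatrix lo(ngrid + 1, n), hi(ngrid + 1, n);
  for (int i = 0; i < n; ++i) { lo(0, i) = sp.H[i].lo; hi(0, i) = sp.H[i].hi; }
  int fail_at = -1;
  for (int node = 1; node <= ngrid; ++node) {
    if (!sp.advance(st.h, 0)) { fail_at = node; break; }
    for (int i = 0; i < n; ++i) {
      lo(node, i) = sp.H[i].lo;
      hi(node, i) = sp.H[i].hi;
    }
  }
  return List::create(_["ok"] = (fail_at < 0), _["fail_at"] = fail_at,
                      _["lo"] = lo, _["hi"] = hi);
}

// [[Rcpp::export]]
int cpp_classify_box(List tape, Nullable<List> gtape, NumericMatrix x0,
                     NumericMatrix pbox, IntegerVector m_gi,
                     IntegerVector m_comp, NumericVector m_lo,
                     NumericVector m_hi, List settings) {
  Tape tp = tape_from_list(tape);
  Tape gt;
  bool have_gt = false;
  if (gtape.isNotNull()) { gt = tape_from_list(gtape.get()); have_gt = true; }
  Settings st = settings_from_list(settings);
  MeasData md = meas_from(m_gi, m_comp, m_lo, m_hi);
  return classify_box_core(tp, have_gt ? &gt : nullptr, mat_to_ivls(x0),
                           mat_to_ivls(pbox), md, st);
}

// [[Rcpp::export]]
List cpp_sivia(List tape, Nullable<List> gtape, NumericMatrix x0,
               NumericMatrix seeds_lo, NumericMatrix seeds_hi,
               IntegerVector m_gi, IntegerVector m_comp, NumericVector m_lo,
               NumericVector m_hi, double eps, double eps_fail,
               List settings) {
  Tape tp = tape_from_list(tape);
  Tape gt;
  bool have_gt = false;
  if (gtape.isNotNull()) { gt = tape_from_list(gtape.get()); have_gt = true; }
  Settings st = settings_from_list(settings);
  MeasData md = meas_from(m_gi, m_comp, m_lo, m_hi);
  std::vector<Ivl> x0v = mat_to_ivls(x0);
  int p = seeds_lo.ncol();

  std::deque<std::vector<Ivl>> queue;
  for (int i = 0; i < seeds_lo.nrow(); ++i) {
    std::vector<Ivl> b(p);
    for (int j = 0; j < p; ++j) b[j] = sd::ivl(seeds_lo(i, j), seeds_hi(i, j));
    queue.push_back(b);
  }

  std::vector<double> out_lo, out_hi;
  std::vector<int> out_status;
  long n_classified = 0, n_failed = 0;

  while (!queue.empty()) {
    std::vector<Ivl> b = queue.front();
    queue.pop_front();
    int cl = classify_box_core(tp, have_gt ? &gt : nullptr, x0v, b, md, st);
    ++n_classified;
    if (n_classified % 256 == 0) Rcpp::checkUserInterrupt();
    if (cl == CL_UNFEASIBLE) continue;
    // widest dimension (ties -> lowest index)
    int wd = 0;
    double wmax = -1.0;
    for (int j = 0; j < p; ++j) {
      double w = sd::iwidth(b[j]);
      if (w > wmax) { wmax = w; wd = j; }
    }
    // indeterminate boxes are bisected to eps; boxes whose enclosure could
    // not be validated carry no classification information and are refined
    // further, to eps_fail (<= eps), where the integrator usually recovers
    double thresh = (cl == CL_FAIL) ? eps_fail : eps;
    if (cl != CL_FEASIBLE && wmax > thresh) {
      double mid = b[wd].lo + 0.5 * (b[wd].hi - b[wd].lo);
      std::vector<Ivl> b1 = b, b2 = b;
      b1[wd].hi = mid;
      b2[wd].lo = mid;
      queue.push_back(b1);
      queue.push_back(b2);
      continue;
    }
    if (cl == CL_FAIL) ++n_failed;
    for (int j = 0; j < p; ++j) {
      out_lo.push_back(b[j].lo);
      out_hi.push_back(b[j].hi);
    }
    out_status.push_back(cl);
  }

  int nb = (int)out_status.size();
  NumericMatrix lo(nb, p), hi(nb, p);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < p; ++j) {
      lo(i, j) = out_lo[(size_t)i * p + j];
      hi(i, j) = out_hi[(size_t)i * p + j];
    }
  return List::create(
      _["lo"] = lo, _["hi"] = hi,
      _["status"] = IntegerVector(out_status.begin(), out_status.end()),
      _["n_classified"] = (double)n_classified,
      _["n_failed"] = (double)n_failed);
}

// [[Rcpp::export]]
List cpp_state_bounds(List tape, NumericMatrix x0, NumericMatrix boxes_lo,
                      NumericMatrix boxes_hi, int ngrid, List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  int n = tp.n_state, nb = boxes_lo.nrow();
  std::vector<Ivl> x0v = mat_to_ivls(x0);
  NumericMatrix lo(ngrid + 1, n), hi(ngrid + 1, n);
  std::fill(lo.begin(), lo.end(), INF);
  std::fill(hi.begin(), hi.end(), -INF);
  LogicalVector box_ok(nb);
  int n_ok = 0;
  for (int bi = 0; bi < nb; ++bi) {
    Rcpp::checkUserInterrupt();
    std::vector<Ivl> pbox(boxes_lo.ncol());
    for (int j = 0; j < boxes_lo.ncol(); ++j)
      pbox[j] = sd::ivl(boxes_lo(bi, j), boxes_hi(bi, j));
    Stepper sp(tp, st);
    sp.init(x0v, pbox);
    std::vector<double> blo((size_t)(ngrid + 1) * n), bhi((size_t)(ngrid + 1) * n);
    bool ok = true;
    for (int i = 0; i < n; ++i) { blo[i] = sp.H[i].lo; bhi[i] = sp.H[i].hi; }
    for (int node = 1; node <= ngrid; ++node) {
      if (!sp.advance(st.h, 0)) { ok = false; break; }
      for (int i = 0; i < n; ++i) {
        blo[(size_t)node * n + i] = sp.H[i].lo;
        bhi[(size_t)node * n + i] = sp.H[i].hi;
      }
    }
    box_ok[bi] = ok;
    if (!ok) continue;
    ++n_ok;
    for (int node = 0; node <= ngrid; ++node)
      for (int i = 0; i < n; ++i) {
        if (blo[(size_t)node * n + i] < lo(node, i))
          lo(node, i) = blo[(size_t)node * n + i];
        if (bhi[(size_t)node * n + i] > hi(node, i))
          hi(node, i) = bhi[(size_t)node * n + i];
      }
  }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["box_ok"] = box_ok,
                      _["n_ok"] = n_ok);
}

// Full per-box state enclosures over the whole grid: for each parameter
// box, propagate once and record the hull of every component at every grid
// node.  Boxes whose enclosure fails part-way keep NA from the failure
// node onwards (fail_node reports it).  This is the workhorse behind the
// case-study fast path: with the per-box envelopes cached, adding a
// candidate measurement reduces to an overlap test per box.
// [[Rcpp::export]]
List cpp_partition_envelopes(List tape, NumericMatrix x0,
                             NumericMatrix boxes_lo, NumericMatrix boxes_hi,
                             int ngrid, List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  int n = tp.n_state, nb = boxes_lo.nrow();
  std::vector<Ivl> x0v = mat_to_ivls(x0);
  List lo_out(n), hi_out(n);
  std::vector<NumericMatrix> los, his;
  for (int i = 0; i < n; ++i) {
    NumericMatrix l(nb, ngrid + 1), h(nb, ngrid + 1);
    std::fill(l.begin(), l.end(), NA_REAL);
    std::fill(h.begin(), h.end(), NA_REAL);
    los.push_back(l);
    his.push_back(h);
  }
  IntegerVector fail_node(nb, -1);
  for (int bi = 0; bi < nb; ++bi) {
    if (bi % 32 == 0) Rcpp::checkUserInterrupt();
    std::vector<Ivl> pbox(boxes_lo.ncol());
    for (int j = 0; j < boxes_lo.ncol(); ++j)
      pbox[j] = sd::ivl(boxes_lo(bi, j), boxes_hi(bi, j));
    Stepper sp(tp, st);
    sp.init(x0v, pbox);
    for (int i = 0; i < n; ++i) {
      los[i](bi, 0) = sp.H[i].lo;
      his[i](bi, 0) = sp.H[i].hi;
    }
    for (int node = 1; node <= ngrid; ++node) {
      if (!sp.advance(st.h, 0)) { fail_node[bi] = node; break; }
      for (int i = 0; i < n; ++i) {
        los[i](bi, node) = sp.H[i].lo;
        his[i](bi, node) = sp.H[i].hi;
      }
    }
  }
  for (int i = 0; i < n; ++i) { lo_out[i] = los[i]; hi_out[i] = his[i]; }
  return List::create(_["lo"] = lo_out, _["hi"] = hi_out,
                      _["fail_node"] = fail_node);
}

// Per-box state enclosures at selected grid nodes: for each parameter box,
// propagate once and record the hull of the requested component at each
// requested node.  Boxes whose enclosure fails before a node get NA there.
// [[Rcpp::export]]
List cpp_box_envelopes(List tape, NumericMatrix x0, NumericMatrix boxes_lo,
                       NumericMatrix boxes_hi, IntegerVector nodes,
                       int component, List settings) {
  Tape tp = tape_from_list(tape);
  Settings st = settings_from_list(settings);
  int nb = boxes_lo.nrow(), nn = nodes.size(), comp = component;
  if (comp < 0 || comp >= tp.n_state) stop("bad component");
  int max_node = 0;
  for (int k = 0; k < nn; ++k) max_node = std::max(max_node, nodes[k]);
  std::vector<Ivl> x0v = mat_to_ivls(x0);
  NumericMatrix lo(nb, nn), hi(nb, nn);
  std::fill(lo.begin(), lo.end(), NA_REAL);
  std::fill(hi.begin(), hi.end(), NA_REAL);
  IntegerVector fail_node(nb, -1);
  for (int bi = 0; bi < nb; ++bi) {
    if (bi % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<Ivl> pbox(boxes_lo.ncol());
    for (int j = 0; j < boxes_lo.ncol(); ++j)
      pbox[j] = sd::ivl(boxes_lo(bi, j), boxes_hi(bi, j));
    Stepper sp(tp, st);
    sp.init(x0v, pbox);
    for (int k = 0; k < nn; ++k)
      if (nodes[k] == 0) { lo(bi, k) = sp.H[comp].lo; hi(bi, k) = sp.H[comp].hi; }
    for (int node = 1; node <= max_node; ++node) {
      if (!sp.advance(st.h, 0)) { fail_node[bi] = node; break; }
      for (int k = 0; k < nn; ++k)
        if (nodes[k] == node) {
          lo(bi, k) = sp.H[comp].lo;
          hi(bi, k) = sp.H[comp].hi;
        }
    }
  }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["fail_node"] = fail_node);
}

// [[Rcpp::export]]
List cpp_growth_bounds(List gtape, NumericMatrix pbox, int n_state) {
  Tape gt = tape_from_list(gtape);
  GrowthBounds gb = growth_bounds(gt, n_state, mat_to_ivls(pbox));
  return List::create(
      _["avail"] = LogicalVector(gb.avail.begin(), gb.avail.end()),
      _["lo"] = NumericVector(gb.glo.begin(), gb.glo.end()),
      _["hi"] = NumericVector(gb.ghi.begin(), gb.ghi.end()));
}
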