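#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Benchmark objectives (ids 1..14). Classical suite: 6 unimodal, 8 multimodal.
// ---------------------------------------------------------------------------

static const double KOWALIK_A[11] = {0.1957, 0.1947, 0.1735, 0.1600, 0.0844,
                                     0.0627, 0.0456, 0.0342, 0.0323, 0.0235,
                                     0.0246};
static const double KOWALIK_B[11] = {4.0,    2.0,    1.0,    0.5,    0.25,
                                     1.0 / 6, 0.125, 0.1,   1.0 / 12, 1.0 / 14,
                                     0.0625};

// penalty term u(x, a, k, m) for the penalized functions
static inline double upen(double x, double a, double k, double m) {
  if (x > a) return k * std::pow(x - a, m);
  if (x < -a) return k * std::pow(-x - a, m);
  return 0.0;
}

double bench_eval(int id, const double* x, int d) {
  double s = 0.0, p = 1.0;
  switch (id) {
    case 1: {  // sphere
      for (int i = 0; i < d; ++i) s += x[i] * x[i];
      return s;
    }
    case 2: {  // Schwefel 2.22
      for (int i = 0; i < d; ++i) { s += std::fabs(x[i]); p *= std::fabs(x[i]); }
      return s + p;
    }
    case 3: {  // Schwefel 1.2
      double c = 0.0;
      for (int i = 0; i < d; ++i) { c += x[i]; s += c * c; }
      return s;
    }
    case 4: {  // Rosenbrock
      for (int i = 0; i + 1 < d; ++i) {
        double t1 = x[i + 1] - x[i] * x[i], t2 = x[i] - 1.0;
        s += 100.0 * t1 * t1 + t2 * t2;
      }
      return s;
    }
    case 5: {  // Schwefel 2.21
      for (int i = 0; i < d; ++i) s = std::max(s, std::fabs(x[i]));
      return s;
    }
    case 6: {  // Step
      for (int i = 0; i < d; ++i) {
        double f = std::floor(x[i] + 0.5);
        s += f * f;
      }
      return s;
    }
    case 7: {  // Rastrigin
      for (int i = 0; i < d; ++i)
        s += x[i] * x[i] - 10.0 * std::cos(2.0 * M_PI * x[i]) + 10.0;
      return s;
    }
    case 8: {  // Griewank
      for (int i = 0; i < d; ++i) {
        s += x[i] * x[i] / 4000.0;
        p *= std::cos(x[i] / std::sqrt((double)(i + 1)));
      }
      return s - p + 1.0;
    }
    case 9: {  // Kowalik (dim 4)
      for (int k = 0; k < 11; ++k) {
        double b = KOWALIK_B[k];
        double num = x[0] * (b * b + b * x[1]);
        double den = b * b + b * x[2] + x[3];
        double r = KOWALIK_A[k] - num / den;
        s += r * r;
      }
      return s;
    }
    case 10: {  // Ackley
      double sc = 0.0;
      for (int i = 0; i < d; ++i) {
        s += x[i] * x[i];
        sc += std::cos(2.0 * M_PI * x[i]);
      }
      return -20.0 * std::exp(-0.2 * std::sqrt(s / d)) - std::exp(sc / d) +
             20.0 + std::exp(1.0);
    }
    case 11: {  // Penalized 1
      double y1 = 1.0 + (x[0] + 1.0) / 4.0;
      double acc = 10.0 * std::pow(std::sin(M_PI * y1), 2.0);
      for (int i = 0; i + 1 < d; ++i) {
        double yi = 1.0 + (x[i] + 1.0) / 4.0;
        double yn = 1.0 + (x[i + 1] + 1.0) / 4.0;
        acc += (yi - 1.0) * (yi - 1.0) *
               (1.0 + 10.0 * std::pow(std::sin(M_PI * yn), 2.0));
      }
      double yd = 1.0 + (x[d - 1] + 1.0) / 4.0;
      acc += (yd - 1.0) * (yd - 1.0);
      s = M_PI / d * acc;
      for (int i = 0; i < d; ++i) s += upen(x[i], 10.0, 100.0, 4.0);
      return s;
    }
    case 12: {  // Penalized 2
      double acc = std::pow(std::sin(3.0 * M_PI * x[0]), 2.0);
      for (int i = 0; i + 1 < d; ++i) {
        double t = x[i] - 1.0;
        acc += t * t * (1.0 + std::pow(std::sin(3.0 * M_PI * x[i + 1]), 2.0));
      }
      double t = x[d - 1] - 1.0;
      acc += t * t * (1.0 + std::pow(std::sin(2.0 * M_PI * x[d - 1]), 2.0));
      s = 0.1 * acc;
      for (int i = 0; i < d; ++i) s += upen(x[i], 5.0, 100.0, 4.0);
      return s;
    }
    case 13: {  // Schaffer (dim 2)
      double r2 = x[0] * x[0] + x[1] * x[1];
      double num = std::pow(std::sin(std::sqrt(r2)), 2.0) - 0.5;
      double den = 1.0 + 0.001 * r2;
      return 0.5 + num / (den * den);
    }
    case 14: {  // sum of increasing powers
      for (int i = 0; i < d; ++i) s += std::pow(std::fabs(x[i]), (double)(i + 2));
      return s;
    }
  }
  stop("unknown benchmark id %d", id);
  return NA_REAL;  // not reached
}

// [[Rcpp::export(name = ".bench_eval_cpp")]]
double bench_eval_cpp(int id, NumericVector x) {
  return bench_eval(id, x.begin(), x.size());
}

// ---------------------------------------------------------------------------
// Codeword penalty objective (continuous position -> penalty against a set)
// base coding: A=0, C=1, G=2, T=3; decode = floor, clamped to [0, 3]
// ---------------------------------------------------------------------------

struct CodesetData {
  std::vector<int> members;     // M x n, row-major
  int M = 0, n = 0, d = 0;
  std::vector<int> gc_allowed;  // indicator over counts 0..n
  bool nl = false, ns2 = false, ns3 = false;
};

static inline void decode_codes(const double* x, int n, int* w) {
  for (int i = 0; i < n; ++i) {
    double v = std::floor(x[i]);
    if (v < 0.0) v = 0.0;
    if (v > 3.0) v = 3.0;
    w[i] = (int)v;
  }
}

static double penalty_codes(const int* w, const CodesetData& cd) {
  const int n = cd.n;
  double pen = 0.0;
  int gc = 0;
  for (int i = 0; i < n; ++i)
    if (w[i] == 1 || w[i] == 2) ++gc;  // C or G
  int dev = n + 1;
  for (int c = 0; c <= n; ++c)
    if (cd.gc_allowed[c] && std::abs(gc - c) < dev) dev = std::abs(gc - c);
  pen += dev;
  if (cd.nl)
    for (int i = 0; i + 1 < n; ++i)
      if (w[i] == w[i + 1]) pen += 1.0;
  if (cd.ns2)
    for (int i = 0; i + 3 < n; ++i)
      if (w[i] == w[i + 2] && w[i + 1] == w[i + 3]) pen += 1.0;
  if (cd.ns3)
    for (int i = 0; i + 5 < n; ++i)
      if (w[i] == w[i + 3] && w[i + 1] == w[i + 4] && w[i + 2] == w[i + 5])
        pen += 1.0;
  for (int m = 0; m < cd.M; ++m) {
    const int* v = &cd.members[(size_t)m * n];
    int h = 0;
    for (int i = 0; i < n; ++i)
      if (v[i] != w[i]) ++h;
    if (h < cd.d) pen += cd.d - h;
    if (h == 0) pen += 1.0;  // duplicate
  }
  return pen;
}

static CodesetData codeset_data_from_list(List data) {
  CodesetData cd;
  IntegerMatrix mem = data["members"];
  cd.M = mem.nrow();
  cd.n = mem.ncol();
  cd.d = as<int>(data["d"]);
  cd.members.resize((size_t)cd.M * cd.n);
  for (int i = 0; i < cd.M; ++i)
    for (int j = 0; j < cd.n; ++j) cd.members[(size_t)i * cd.n + j] = mem(i, j);
  IntegerVector gc = data["gc_allowed"];  // length n+1 indicator
  cd.gc_allowed.assign(gc.begin(), gc.end());
  cd.nl = as<bool>(data["nl"]);
  cd.ns2 = as<bool>(data["ns2"]);
  cd.ns3 = as<bool>(data["ns3"]);
  return cd;
}

// [[Rcpp::export(name = ".codeset_penalty_cpp")]]
double codeset_penalty_cpp(NumericVector x, List data) {
  CodesetData cd = codeset_data_from_list(data);
  if ((int)x.size() != cd.n) stop("position length does not match word length");
  std::vector<int> w(cd.n);
  decode_codes(x.begin(), cd.n, w.data());
  return penalty_codes(w.data(), cd);
}

// ---------------------------------------------------------------------------
// CLGBO core: GBO (gradient search rule + local escape operator) with Cauchy
// and Levy mutation and greedy survivor selection. Uses R's RNG throughout so
// set.seed() makes runs bit-reproducible.
// ---------------------------------------------------------------------------

struct Objective {
  int id;  // 0 = R function, 1..14 builtin benchmark, 100 = codeset penalty
  Function rfun;
  CodesetData cd;
  long long evals;
  Objective(int id_, SEXP rf, List data) : id(id_), rfun(rf), evals(0) {
    if (id == 100) cd = codeset_data_from_list(data);
  }
  double eval(const std::vector<double>& x) {
    ++evals;
    double f;
    if (id == 0) {
      NumericVector xv(x.begin(), x.end());
      f = as<double>(rfun(xv));
    } else if (id == 100) {
      std::vector<int> w(cd.n);
      decode_codes(x.data(), cd.n, w.data());
      f = penalty_codes(w.data(), cd);
    } else {
      f = bench_eval(id, x.data(), (int)x.size());
    }
    if (!R_FINITE(f)) {
      std::string msg = "objective returned a non-finite value at position (";
      for (size_t i = 0; i < x.size() && i < 8; ++i) {
        if (i) msg += ", ";
        msg += std::to_string(x[i]);
      }
      if (x.size() > 8) msg += ", ...";
      msg += ")";
      stop(msg);
    }
    return f;
  }
};

static inline double runif01() { return unif_rand(); }

static inline double cauchy_draw() {
  // gamma = tan(pi * (u - 1/2)); u in (0,1) a.s.
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return std::tan(M_PI * (u - 0.5));
}

static inline double levy_draw(double phi, double inv_beta) {
  double mu = norm_rand();
  double nu = std::fabs(norm_rand());
  return phi * mu / std::pow(nu, inv_beta);
}

// [[Rcpp::export(name = ".clgbo_core")]]
List clgbo_core(int obj_id, SEXP obj_fun, List obj_data, NumericVector lower,
                NumericVector upper, int n_pop, int max_iter, double pr,
                double levy_beta, double beta_min, double beta_max,
                int mut_mode, bool per_coord, bool mutate_best,
                double stop_at) {
  const int d = lower.size();
  if (upper.size() != d) stop("lower/upper length mismatch");
  for (int j = 0; j < d; ++j)
    if (!(lower[j] < upper[j])) stop("need lower < upper in every dimension");
  if (n_pop < 2) stop("population size must be >= 2");
  if (max_iter < 1) stop("max_iter must be >= 1");

  Objective obj(obj_id, obj_fun, obj_data);

  const double phi =
      std::pow(std::tgamma(1.0 + levy_beta) * std::sin(M_PI * levy_beta / 2.0) /
                   (std::tgamma((1.0 + levy_beta) / 2.0) * levy_beta *
                    std::pow(2.0, (levy_beta - 1.0) / 2.0)),
               1.0 / levy_beta);
  const double inv_beta = 1.0 / levy_beta;

  std::vector<std::vector<double>> X(n_pop, std::vector<double>(d));
  std::vector<double> cost(n_pop);
  for (int i = 0; i < n_pop; ++i) {
    for (int j = 0; j < d; ++j)
      X[i][j] = lower[j] + unif_rand() * (upper[j] - lower[j]);
    cost[i] = obj.eval(X[i]);
  }
  std::vector<double> best_x = X[0], worst_x = X[0];
  double best_c = cost[0], worst_c = cost[0];
  for (int i = 1; i < n_pop; ++i) {
    if (cost[i] < best_c) { best_c = cost[i]; best_x = X[i]; }
    if (cost[i] > worst_c) { worst_c = cost[i]; worst_x = X[i]; }
  }

  std::vector<double> curve;
  curve.reserve(max_iter);
  long long leo_count = 0;
  std::vector<double> x1(d), x2(d), xn(d), delx(d), cand(d);

  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double beta = beta_min + (beta_max - beta_min) *
                                 std::pow(1.0 - std::pow((double)it / max_iter, 3.0), 2.0);
    double alpha =
        std::fabs(beta * std::sin(1.5 * M_PI + std::sin(1.5 * M_PI * beta)));
    for (int i = 0; i < n_pop; ++i) {
      int r1 = std::min((int)(unif_rand() * n_pop), n_pop - 1);
      int r2 = std::min((int)(unif_rand() * n_pop), n_pop - 1);
      int r3 = std::min((int)(unif_rand() * n_pop), n_pop - 1);
      int r4 = std::min((int)(unif_rand() * n_pop), n_pop - 1);
      double ro = alpha * (2.0 * unif_rand() - 1.0);
      double ro1 = alpha * (2.0 * unif_rand() - 1.0);
      double epsv = 5e-3 * unif_rand();

      // gradient search rule step sizes
      double rnd_delta = unif_rand();
      double randn1 = norm_rand(), randn2 = norm_rand();
      double yr1 = unif_rand(), yr2 = unif_rand(), yr3 = unif_rand(),
             yr4 = unif_rand();
      double dm1r = unif_rand(), dm2r = unif_rand();
      for (int j = 0; j < d; ++j) {
        double xm = (X[r1][j] + X[r2][j] + X[r3][j] + X[r4][j]) / 4.0;
        double delta = 2.0 * rnd_delta * std::fabs(xm - X[i][j]);
        double step = ((best_x[j] - X[r1][j]) + delta) / 2.0;
        delx[j] = unif_rand() * std::fabs(step);
        // current-anchored move
        double dm = dm1r * ro * (best_x[j] - X[i][j]);
        double xs = X[i][j] - randn1 * ro1 * (2.0 * delx[j] * X[i][j]) /
                                  (best_x[j] - worst_x[j] + epsv) +
                    dm;
        double yp = yr1 * (0.5 * (xs + X[i][j]) + yr2 * delx[j]);
        double yq = yr1 * (0.5 * (xs + X[i][j]) - yr2 * delx[j]);
        double gsr = randn1 * ro1 * (2.0 * delx[j] * X[i][j]) / (yp - yq + epsv);
        x1[j] = X[i][j] - gsr + dm;
        // best-anchored move
        double dm2 = dm2r * ro * (X[r1][j] - X[r2][j]);
        double xs2 = best_x[j] - randn2 * ro1 * (2.0 * delx[j] * X[i][j]) /
                                     (best_x[j] - worst_x[j] + epsv) +
                     dm2;
        double yp2 = yr3 * (0.5 * (xs2 + X[i][j]) + yr4 * delx[j]);
        double yq2 = yr3 * (0.5 * (xs2 + X[i][j]) - yr4 * delx[j]);
        double gsr2 =
            randn2 * ro1 * (2.0 * delx[j] * X[i][j]) / (yp2 - yq2 + epsv);
        x2[j] = best_x[j] - gsr2 + dm2;
      }
      double ra = unif_rand(), rb = unif_rand();
      for (int j = 0; j < d; ++j) {
        double x3 = X[i][j] - ro1 * (x2[j] - x1[j]);
        xn[j] = ra * (rb * x1[j] + (1.0 - rb) * x2[j]) + (1.0 - ra) * x3;
      }

      // local escape operator
      if (unif_rand() < pr) {
        ++leo_count;
        double f1 = -1.0 + 2.0 * unif_rand();
        double f2 = -1.0 + 2.0 * unif_rand();
        double ro_l = alpha * (2.0 * unif_rand() - 1.0);
        int k = std::min((int)(unif_rand() * n_pop), n_pop - 1);
        bool l1 = unif_rand() < 0.5;
        double u1 = l1 ? 2.0 * unif_rand() : 1.0;
        double u2 = l1 ? unif_rand() : 1.0;
        double u3 = l1 ? unif_rand() : 1.0;
        bool l2 = unif_rand() < 0.5;
        bool anchor_new = unif_rand() < 0.5;
        for (int j = 0; j < d; ++j) {
          double xrand = lower[j] + unif_rand() * (upper[j] - lower[j]);
          double xp = l2 ? xrand : X[k][j];
          double move = f1 * (u1 * best_x[j] - u2 * xp) +
                        f2 * ro_l *
                            (u3 * (x2[j] - x1[j]) + u2 * (X[r1][j] - X[r2][j])) /
                            2.0;
          xn[j] = (anchor_new ? xn[j] : best_x[j]) + move;
        }
      }

      for (int j = 0; j < d; ++j) {
        if (xn[j] < lower[j]) xn[j] = lower[j];
        if (xn[j] > upper[j]) xn[j] = upper[j];
      }
      double fn = obj.eval(xn);
      if (fn < cost[i]) {
        X[i] = xn;
        cost[i] = fn;
        if (fn < best_c) { best_c = fn; best_x = X[i]; }
      }
      if (cost[i] > worst_c) { worst_c = cost[i]; worst_x = X[i]; }

      // Cauchy mutation (around the best individual by default, so the
      // population keeps probing the neighbourhood of the incumbent optimum)
      const std::vector<double>& base = mutate_best ? best_x : X[i];
      if (mut_mode & 1) {
        double cs = per_coord ? 0.0 : cauchy_draw();
        for (int j = 0; j < d; ++j) {
          double c = per_coord ? cauchy_draw() : cs;
          double v = base[j] + base[j] * c;
          if (v < lower[j]) v = lower[j];
          if (v > upper[j]) v = upper[j];
          cand[j] = v;
        }
        double fc = obj.eval(cand);
        if (fc < cost[i]) {
          X[i] = cand;
          cost[i] = fc;
          if (fc < best_c) { best_c = fc; best_x = X[i]; }
        }
      }
      // Levy mutation
      if (mut_mode & 2) {
        double ls = per_coord ? 0.0 : levy_draw(phi, inv_beta);
        for (int j = 0; j < d; ++j) {
          double l = per_coord ? levy_draw(phi, inv_beta) : ls;
          double v = base[j] + base[j] * l;
          if (v < lower[j]) v = lower[j];
          if (v > upper[j]) v = upper[j];
          cand[j] = v;
        }
        double fl = obj.eval(cand);
        if (fl < cost[i]) {
          X[i] = cand;
          cost[i] = fl;
          if (fl < best_c) { best_c = fl; best_x = X[i]; }
        }
      }
    }
    curve.push_back(best_c);
    if (best_c <= stop_at) break;
  }

  return List::create(
      _["best"] = NumericVector(best_x.begin(), best_x.end()),
      _["value"] = best_c,
      _["curve"] = NumericVector(curve.begin(), curve.end()),
      _["evaluations"] = (double)obj.evals,
      _["iterations"] = (double)curve.size(),
      _["leo_entries"] = (double)leo_count);
}

// ---------------------------------------------------------------------------
// Exact maximum clique (branch and bound with greedy-coloring bound) on the
// compatibility graph of feasible codewords: edge iff Hamming distance >= d.
// ---------------------------------------------------------------------------

typedef unsigned long long word_t;

struct CliqueSearch {
  int n, nw;                         // vertices, 64-bit words per row
  std::vector<word_t> adj;           // n rows of nw words (bitset adjacency)
  std::vector<int> best, cur;
  long long nodes = 0, budget = 0;
  bool aborted = false;

  inline const word_t* row(int v) const { return &adj[(size_t)v * nw]; }

  static inline int first_bit(const word_t* s, int nw) {
    for (int w = 0; w < nw; ++w)
      if (s[w]) return w * 64 + __builtin_ctzll(s[w]);
    return -1;
  }

  // Tomita-style: greedy-color the candidate set, then branch from the
  // highest color downward; color number bounds the clique extension
  void expand(std::vector<word_t>& P) {
    if (aborted) return;
    if (++nodes > budget) { aborted = true; return; }
    std::vector<int> order, colors;
    {
      std::vector<word_t> Q(P), avail(nw);
      int color = 0;
      while (true) {
        int v0 = first_bit(Q.data(), nw);
        if (v0 < 0) break;
        ++color;
        std::copy(Q.begin(), Q.end(), avail.begin());
        while (true) {
          int v = first_bit(avail.data(), nw);
          if (v < 0) break;
          const word_t* nb = row(v);
          for (int w = 0; w < nw; ++w) avail[w] &= ~nb[w];
          avail[v >> 6] &= ~(word_t(1) << (v & 63));
          Q[v >> 6] &= ~(word_t(1) << (v & 63));
          order.push_back(v);
          colors.push_back(color);
        }
      }
    }
    std::vector<word_t> Pn(nw);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      if ((int)cur.size() + colors[i] <= (int)best.size()) return;
      int v = order[i];
      const word_t* nb = row(v);
      bool empty = true;
      for (int w = 0; w < nw; ++w) {
        Pn[w] = P[w] & nb[w];
        if (Pn[w]) empty = false;
      }
      cur.push_back(v);
      if (empty) {
        if (cur.size() > best.size()) best = cur;
      } else {
        std::vector<word_t> Pn_copy(Pn);
        expand(Pn_copy);
      }
      cur.pop_back();
      P[v >> 6] &= ~(word_t(1) << (v & 63));
      if (aborted) return;
    }
  }
};

// [[Rcpp::export(name = ".max_clique_cpp")]]
List max_clique_cpp(IntegerMatrix codes, int d, double node_budget) {
  const int m = codes.nrow(), n = codes.ncol();
  // order vertices by degree (descending) for tighter early coloring
  std::vector<std::vector<char>> dense(m, std::vector<char>(m, 0));
  std::vector<int> deg(m, 0);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      int h = 0;
      for (int j = 0; j < n; ++j)
        if (codes(a, j) != codes(b, j)) ++h;
      if (h >= d) {
        dense[a][b] = dense[b][a] = 1;
        ++deg[a];
        ++deg[b];
      }
    }
  std::vector<int> perm(m);
  for (int i = 0; i < m; ++i) perm[i] = i;
  std::sort(perm.begin(), perm.end(),
            [&](int a, int b) { return deg[a] > deg[b]; });

  CliqueSearch cs;
  cs.n = m;
  cs.nw = (m + 63) / 64;
  cs.budget = (long long)node_budget;
  cs.adj.assign((size_t)m * cs.nw, 0);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (dense[perm[a]][perm[b]])
        cs.adj[(size_t)a * cs.nw + (b >> 6)] |= word_t(1) << (b & 63);

  std::vector<word_t> P(cs.nw, 0);
  for (int i = 0; i < m; ++i) P[i >> 6] |= word_t(1) << (i & 63);
  if (m > 0) cs.expand(P);
  IntegerVector clique(cs.best.size());
  for (size_t i = 0; i < cs.best.size(); ++i)
    clique[i] = perm[cs.best[i]] + 1;
  return List::create(_["clique"] = clique, _["complete"] = !cs.aborted,
                      _["nodes"] = (double)cs.nodes);
}

// [[Rcpp::export(name = ".hamming_matrix_cpp")]]
IntegerMatrix hamming_matrix_cpp(IntegerMatrix codes) {
  const int m = codes.nrow(), n = codes.ncol();
  IntegerMatrix H(m, m);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      int h = 0;
      for (int j = 0; j < n; ++j)
        if (codes(a, j) != codes(b, j)) ++h;
      H(a, b) = h;
      H(b, a) = h;
    }
  return H;
}
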