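// Stochastic simulation engines: non-spatial agent-based model (random
// groups of N drawn from a finite population) and the spatially explicit
// toroidal lattice model (Moore-neighborhood groups, adjacent-pair
// imitation, Poisson diffusion swaps). Genotypes are bit codes:
// C = 1, S = 2, R = 4. All randomness comes from R's RNG, so runs are
// reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int hasC(int g) { return g & 1; }
static inline int hasS(int g) { return (g >> 1) & 1; }
static inline int hasR(int g) { return (g >> 2) & 1; }

struct GamePar {
  double c0, c, s, r, b, sigma, D, dmax;
  int Q, kappa;
  double mu[6]; // C_loss, C_gain, S_loss, S_gain, R_loss, R_gain
  bool any_mu;
  int diffusion_poisson; // 1 = Poisson(D), 0 = floor(D) + Bernoulli
  int pair_moore;        // 1 = Moore (8), 0 = von Neumann (4)
};

static GamePar read_par(const List& par) {
  GamePar p;
  p.c0 = as<double>(par["c0"]);
  p.c = as<double>(par["c"]);
  p.s = as<double>(par["s"]);
  p.r = as<double>(par["r"]);
  p.b = as<double>(par["b"]);
  p.sigma = as<double>(par["sigma"]);
  p.D = as<double>(par["D"]);
  p.Q = as<int>(par["Q"]);
  p.kappa = as<int>(par["kappa"]);
  NumericVector mu = par["mu"];
  p.any_mu = false;
  for (int i = 0; i < 6; i++) {
    p.mu[i] = mu[i];
    if (mu[i] > 0) p.any_mu = true;
  }
  p.dmax = p.c + p.s + p.r + p.b * p.c0;
  p.diffusion_poisson = as<int>(par["diffusion_poisson"]);
  p.pair_moore = as<int>(par["pair_moore"]);
  return p;
}

static inline int mutate_code(int g, const GamePar& p) {
  // locus order C, S, R; bit k has loss rate mu[2k], gain rate mu[2k+1]
  for (int k = 0; k < 3; k++) {
    int bit = 1 << k;
    double rate = (g & bit) ? p.mu[2 * k] : p.mu[2 * k + 1];
    if (rate > 0 && unif_rand() < rate) g ^= bit;
  }
  return g;
}

// winner-takes-slot imitation between agents with costs ci, cj;
// returns 1 if i wins, 0 if j wins
static inline int imitation_winner(double ci, double cj, const GamePar& p) {
  double dw = (cj - ci) / p.dmax;
  double prob = 0.5 * (1.0 + p.sigma * dw);
  if (prob < 0) prob = 0;
  if (prob > 1) prob = 1;
  return unif_rand() < prob ? 1 : 0;
}

// ---------------------------------------------------------------------------
// Non-spatial ABM: shared-pool activation within each sampled group

// realized cost of the focal (slot 0) of a group of N codes
static double group_focal_cost(const int* grp, int N, const GamePar& p) {
  int doses = 0;
  for (int k = 0; k < N; k++) doses += hasC(grp[k]) + hasS(grp[k]);
  int active = doses >= p.Q;
  int n_active = 0;
  for (int k = 0; k < N; k++) {
    if (hasC(grp[k])) {
      if (!hasR(grp[k]) || active) n_active++;
    }
  }
  int theta = n_active >= p.kappa ? 1 : 0;
  int f = grp[0];
  int gamma_f = hasC(f) ? (!hasR(f) || active ? 1 : 0) : 0;
  return (1.0 - theta * p.b) *
         (p.c0 + gamma_f * p.c + p.s * hasS(f) + p.r * hasR(f));
}

// draw n distinct indices from 0..P-1 by rejection (n << P)
static void sample_distinct(int P, int n, int* out) {
  for (int k = 0; k < n; k++) {
    int cand;
    bool dup;
    do {
      cand = (int)(unif_rand() * P);
      if (cand >= P) cand = P - 1;
      dup = false;
      for (int q = 0; q < k; q++) {
        if (out[q] == cand) { dup = true; break; }
      }
    } while (dup);
    out[k] = cand;
  }
}

// [[Rcpp::export(name = ".abm_engine")]]
List abm_engine(IntegerVector pop0, List par, int N, int n_gen,
                int record_every) {
  GamePar p = read_par(par);
  std::vector<int> pop(pop0.begin(), pop0.end());
  int P = pop.size();
  long steps_per_gen = P / 2;
  int n_rec = n_gen / record_every + 1;
  NumericMatrix freq(n_rec, 8);
  IntegerVector rec_gen(n_rec);
  std::vector<int> code_of(8);
  // canonical genotype order La Tr Bo Sm Ne Li Cl Vo
  int canon[8] = {0, 1, 3, 5, 7, 2, 6, 4};
  std::vector<int> col_of(8);
  for (int i = 0; i < 8; i++) col_of[canon[i]] = i;

  std::vector<int> grp_i(N), grp_j(N);
  std::vector<int> idx_i(N), idx_j(N);

  int rec = 0;
  // record initial state
  {
    std::vector<long> cnt(8, 0);
    for (int a = 0; a < P; a++) cnt[pop[a]]++;
    for (int g = 0; g < 8; g++) freq(rec, col_of[g]) = (double)cnt[g] / P;
    rec_gen[rec] = 0;
    rec++;
  }

  for (int gen = 1; gen <= n_gen; gen++) {
    for (long st = 0; st < steps_per_gen; st++) {
      sample_distinct(P, N, idx_i.data());
      sample_distinct(P, N, idx_j.data());
      for (int k = 0; k < N; k++) {
        grp_i[k] = pop[idx_i[k]];
        grp_j[k] = pop[idx_j[k]];
      }
      double ci = group_focal_cost(grp_i.data(), N, p);
      double cj = group_focal_cost(grp_j.data(), N, p);
      int fi = idx_i[0], fj = idx_j[0];
      if (imitation_winner(ci, cj, p)) {
        pop[fj] = p.any_mu ? mutate_code(pop[fi], p) : pop[fi];
      } else {
        pop[fi] = p.any_mu ? mutate_code(pop[fj], p) : pop[fj];
      }
    }
    if (gen % record_every == 0) {
      std::vector<long> cnt(8, 0);
      for (int a = 0; a < P; a++) cnt[pop[a]]++;
      for (int g = 0; g < 8; g++) freq(rec, col_of[g]) = (double)cnt[g] / P;
      rec_gen[rec] = gen;
      rec++;
    }
  }
  return List::create(_["freq"] = freq, _["generation"] = rec_gen,
                      _["pop"] = IntegerVector(pop.begin(), pop.end()));
}

// ---------------------------------------------------------------------------
// Lattice model: per-agent activation against its OWN Moore neighborhood

struct Lattice {
  int M;
  std::vector<int> g;
  std::vector<int> up, down; // wrapped row/col index shifts
  Lattice(IntegerMatrix grid) {
    M = grid.nrow();
    g.resize((size_t)M * M);
    for (int i = 0; i < M; i++)
      for (int j = 0; j < M; j++) g[(size_t)i * M + j] = grid(i, j);
    up.resize(M); down.resize(M);
    for (int i = 0; i < M; i++) {
      up[i] = (i == 0) ? M - 1 : i - 1;
      down[i] = (i == M - 1) ? 0 : i + 1;
    }
  }
  inline int at(int i, int j) const { return g[(size_t)i * M + j]; }
  inline void set(int i, int j, int v) { g[(size_t)i * M + j] = v; }
};

// signal doses within the Moore neighborhood centered on (i, j)
static inline int doses_own(const Lattice& L, int i, int j) {
  int rows[3] = {L.up[i], i, L.down[i]};
  int cols[3] = {L.up[j], j, L.down[j]};
  int d = 0;
  for (int a = 0; a < 3; a++)
    for (int b = 0; b < 3; b++) {
      int gg = L.at(rows[a], cols[b]);
      d += hasC(gg) + hasS(gg);
    }
  return d;
}

// realized cost of the agent at (i, j): each conditional cooperator in the
// focal's group evaluates Q against its own neighborhood doses
static double lattice_cost(const Lattice& L, int i, int j, const GamePar& p) {
  int rows[3] = {L.up[i], i, L.down[i]};
  int cols[3] = {L.up[j], j, L.down[j]};
  int n_active = 0;
  int gamma_f = 0;
  for (int a = 0; a < 3; a++) {
    for (int b = 0; b < 3; b++) {
      int mi = rows[a], mj = cols[b];
      int gg = L.at(mi, mj);
      int gam = 0;
      if (hasC(gg)) {
        if (!hasR(gg)) gam = 1;
        else gam = doses_own(L, mi, mj) >= p.Q ? 1 : 0;
      }
      n_active += gam;
      if (mi == i && mj == j) gamma_f = gam;
    }
  }
  int theta = n_active >= p.kappa ? 1 : 0;
  int f = L.at(i, j);
  return (1.0 - theta * p.b) *
         (p.c0 + gamma_f * p.c + p.s * hasS(f) + p.r * hasR(f));
}

// pick a random adjacent site of (i, j); Moore (8) or von Neumann (4)
static inline void random_neighbor(const Lattice& L, int i, int j, int moore,
                                   int* ni, int* nj) {
  if (moore) {
    static const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int k = (int)(unif_rand() * 8);
    if (k > 7) k = 7;
    *ni = di[k] < 0 ? L.up[i] : (di[k] > 0 ? L.down[i] : i);
    *nj = dj[k] < 0 ? L.up[j] : (dj[k] > 0 ? L.down[j] : j);
  } else {
    static const int di[4] = {-1, 1, 0, 0};
    static const int dj[4] = {0, 0, -1, 1};
    int k = (int)(unif_rand() * 4);
    if (k > 3) k = 3;
    *ni = di[k] < 0 ? L.up[i] : (di[k] > 0 ? L.down[i] : i);
    *nj = dj[k] < 0 ? L.up[j] : (dj[k] > 0 ? L.down[j] : j);
  }
}

static void diffusion_sweep(Lattice& L, const GamePar& p) {
  int n_swaps;
  if (p.diffusion_poisson) {
    n_swaps = (int)R::rpois(p.D);
  } else {
    n_swaps = (int)std::floor(p.D);
    double frac = p.D - n_swaps;
    if (frac > 0 && unif_rand() < frac) n_swaps++;
  }
  for (int sw = 0; sw < n_swaps; sw++) {
    int i = (int)(unif_rand() * L.M); if (i >= L.M) i = L.M - 1;
    int j = (int)(unif_rand() * L.M); if (j >= L.M) j = L.M - 1;
    int ni, nj;
    random_neighbor(L, i, j, p.pair_moore, &ni, &nj);
    int tmp = L.at(i, j);
    L.set(i, j, L.at(ni, nj));
    L.set(ni, nj, tmp);
  }
}

// [[Rcpp::export(name = ".lattice_engine")]]
List lattice_engine(IntegerMatrix grid0, List par, int n_gen,
                    int record_every, int snapshot_every) {
  GamePar p = read_par(par);
  Lattice L(grid0);
  int M = L.M;
  long pop = (long)M * M;
  long steps_per_gen = pop / 2;
  int n_rec = n_gen / record_every + 1;
  NumericMatrix freq(n_rec, 8);
  IntegerVector rec_gen(n_rec);
  int canon[8] = {0, 1, 3, 5, 7, 2, 6, 4};
  std::vector<int> col_of(8);
  for (int i = 0; i < 8; i++) col_of[canon[i]] = i;
  List snapshots;

  int rec = 0;
  {
    std::vector<long> cnt(8, 0);
    for (long a = 0; a < pop; a++) cnt[L.g[a]]++;
    for (int g = 0; g < 8; g++) freq(rec, col_of[g]) = (double)cnt[g] / pop;
    rec_gen[rec] = 0;
    rec++;
  }

  for (int gen = 1; gen <= n_gen; gen++) {
    for (long st = 0; st < steps_per_gen; st++) {
      int i = (int)(unif_rand() * M); if (i >= M) i = M - 1;
      int j = (int)(unif_rand() * M); if (j >= M) j = M - 1;
      int ni, nj;
      random_neighbor(L, i, j, p.pair_moore, &ni, &nj);
      double ci = lattice_cost(L, i, j, p);
      double cj = lattice_cost(L, ni, nj, p);
      if (imitation_winner(ci, cj, p)) {
        int off = L.at(i, j);
        L.set(ni, nj, p.any_mu ? mutate_code(off, p) : off);
      } else {
        int off = L.at(ni, nj);
        L.set(i, j, p.any_mu ? mutate_code(off, p) : off);
      }
      if (p.D > 0) diffusion_sweep(L, p);
    }
    if (gen % record_every == 0) {
      std::vector<long> cnt(8, 0);
      for (long a = 0; a < pop; a++) cnt[L.g[a]]++;
      for (int g = 0; g < 8; g++) freq(rec, col_of[g]) = (double)cnt[g] / pop;
      rec_gen[rec] = gen;
      rec++;
    }
    if (snapshot_every > 0 && gen % snapshot_every == 0) {
      IntegerMatrix snap(M, M);
      for (int a = 0; a < M; a++)
        for (int b = 0; b < M; b++) snap(a, b) = L.at(a, b);
      snapshots.push_back(snap);
    }
  }

  IntegerMatrix out_grid(M, M);
  for (int a = 0; a < M; a++)
    for (int b = 0; b < M; b++) out_grid(a, b) = L.at(a, b);
  return List::create(_["freq"] = freq, _["generation"] = rec_gen,
                      _["grid"] = out_grid, _["snapshots"] = snapshots);
}

// Full matrix of realized site costs (reference cross-check for the R
// implementation of site_cost)
// [[Rcpp::export(name = ".lattice_site_costs")]]
NumericMatrix lattice_site_costs(IntegerMatrix grid, List par) {
  GamePar p = read_par(par);
  Lattice L(grid);
  NumericMatrix out(L.M, L.M);
  for (int i = 0; i < L.M; i++)
    for (int j = 0; j < L.M; j++) out(i, j) = lattice_cost(L, i, j, p);
  return out;
}

// Standalone diffusion pass over n_steps game-step equivalents (each draws
// its own swap count); used for the Poisson swap-count checks
// [[Rcpp::export(name = ".diffusion_engine")]]
List diffusion_engine(IntegerMatrix grid0, List par, int n_steps) {
  GamePar p = read_par(par);
  Lattice L(grid0);
  long total_swaps = 0;
  for (int st = 0; st < n_steps; st++) {
    // count swaps by re-deriving the draw (mirrors diffusion_sweep)
    int n_swaps;
    if (p.diffusion_poisson) {
      n_swaps = (int)R::rpois(p.D);
    } else {
      n_swaps = (int)std::floor(p.D);
      double frac = p.D - n_swaps;
      if (frac > 0 && unif_rand() < frac) n_swaps++;
    }
    total_swaps += n_swaps;
    for (int sw = 0; sw < n_swaps; sw++) {
      int i = (int)(unif_rand() * L.M); if (i >= L.M) i = L.M - 1;
      int j = (int)(unif_rand() * L.M); if (j >= L.M) j = L.M - 1;
      int ni, nj;
      random_neighbor(L, i, j, p.pair_moore, &ni, &nj);
      int tmp = L.at(i, j);
      L.set(i, j, L.at(ni, nj));
      L.set(ni, nj, tmp);
    }
  }
  IntegerMatrix out_grid(L.M, L.M);
  for (int a = 0; a < L.M; a++)
    for (int b = 0; b < L.M; b++) out_grid(a, b) = L.at(a, b);
  return List::create(_["grid"] = out_grid, _["total_swaps"] = total_swaps);
}
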