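// Core discrete-time engine for the foraging agent-based model.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// fully determines a run.  The per-tick schedule, in uniformly shuffled agent
// order, is: move (predation) -> forage/eat -> share -> metabolise
// (exhaustion) -> adapt -> reproduce (birth death) -> old-age check; then the
// environment regrows.  Death cause codes: 1 = OLD_AGE, 2 = EXHAUSTION,
// 3 = PREDATION, 4 = BIRTH.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double GRID_TOL = 1e-9;

struct Cfg {
  int W, H;
  double Fmax, regrow_n, regrow_s, recov_p;
  int n_pred;
  double f2e, Emax, Smax, living, refill_thr, repro_frac;
  int age_min, age_max;
  double birth_cost, birth_transfer;
  int old_thr;
  double old_p;
  double mut_step, mut_down, mut_up;
  double share_store_frac, share_energy_mult, share_amount;
  int share_radius;
  double innov_p;
  int vic_radius, ledger_window, skew_thr;
  int init_pop;
  double e0_lo, e0_hi;
  double f0_lo, f0_hi;
  int run_length, shock_tick;
  double wb_mult;
};

static Cfg parse_cfg(const List& c) {
  Cfg g;
  g.W = as<int>(c["grid_width"]);
  g.H = as<int>(c["grid_height"]);
  g.Fmax = as<double>(c["max_food_per_patch"]);
  g.regrow_n = as<double>(c["regrowth_normal"]);
  g.regrow_s = as<double>(c["regrowth_shocked"]);
  g.recov_p = as<double>(c["recovery_prob"]);
  g.n_pred = as<int>(c["n_predator_patches"]);
  g.f2e = as<double>(c["food_to_energy"]);
  g.Emax = as<double>(c["energy_capacity"]);
  g.Smax = as<double>(c["storage_capacity"]);
  g.living = as<double>(c["living_cost"]);
  g.refill_thr = as<double>(c["refill_threshold"]);
  g.repro_frac = as<double>(c["repro_energy_fraction"]);
  g.age_min = as<int>(c["repro_age_min"]);
  g.age_max = as<int>(c["repro_age_max"]);
  g.birth_cost = as<double>(c["birth_cost"]);
  g.birth_transfer = as<double>(c["birth_transfer"]);
  g.old_thr = as<int>(c["old_age_threshold"]);
  g.old_p = as<double>(c["old_age_death_prob"]);
  g.mut_step = as<double>(c["mutation_step"]);
  g.mut_down = as<double>(c["mutation_down_prob"]);
  g.mut_up = as<double>(c["mutation_up_prob"]);
  g.share_store_frac = as<double>(c["share_donor_store_fraction"]);
  g.share_energy_mult = as<double>(c["share_recipient_energy_multiple"]);
  g.share_amount = as<double>(c["share_amount"]);
  g.share_radius = as<int>(c["share_radius"]);
  g.innov_p = as<double>(c["innovation_prob"]);
  g.vic_radius = as<int>(c["vicinity_radius"]);
  g.ledger_window = as<int>(c["ledger_window"]);
  g.skew_thr = as<int>(c["ledger_skew_threshold"]);
  g.init_pop = as<int>(c["init_population"]);
  NumericVector er = c["init_energy_range"];
  g.e0_lo = er[0]; g.e0_hi = er[1];
  NumericVector fr = c["init_food_range"];
  g.f0_lo = fr[0]; g.f0_hi = fr[1];
  g.run_length = as<int>(c["run_length"]);
  g.shock_tick = as<int>(c["shock_tick"]);
  g.wb_mult = as<double>(c["wellbeing_energy_multiple"]);
  return g;
}

// snap a foraging fraction to the 0.1 grid (guards against fp drift)
static inline double grid_snap(double f) { return std::round(f * 10.0) / 10.0; }

static inline int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Mutation kernel: -step with prob mut_down, +step with prob mut_up, else
// unchanged; a step leaving [0,1] is cancelled (child keeps parent's value).
static double mutate_one(double v, const Cfg& g) {
  double u = unif_rand();
  double nv = v;
  if (u < g.mut_down) nv = v - g.mut_step;
  else if (u < g.mut_down + g.mut_up) nv = v + g.mut_step;
  if (nv < -GRID_TOL || nv > 1.0 + GRID_TOL) nv = v;
  return grid_snap(nv);
}

struct ForageResult {
  double store, energy, food;
  bool denuded;
  double eaten, cap_loss;
};

// take = frac * food; store what fits, eat the surplus (capped at Emax);
// the patch is denuded when a take leaves food at exactly 0 from food > 0.
static ForageResult forage_eat(double frac, double food, double store,
                               double energy, const Cfg& g) {
  ForageResult r;
  double take = frac * food;
  double to_store = std::min(take, g.Smax - store);
  if (to_store < 0) to_store = 0;
  double surplus = take - to_store;
  r.store = store + to_store;
  double gain = surplus * g.f2e;
  double room = g.Emax - energy;
  if (gain > room) { r.cap_loss = gain - room; gain = room; }
  else r.cap_loss = 0.0;
  r.energy = energy + gain;
  r.eaten = surplus;
  r.food = food - take;
  r.denuded = (food > GRID_TOL) && (r.food <= GRID_TOL);
  if (r.food < 0) r.food = 0;
  if (r.denuded) r.food = 0;
  return r;
}

struct MetabResult {
  double energy, store, refill_food;
  bool died;
};

// pay the living cost; below the refill threshold eat from the store
// (up to Emax); at energy <= 0 the agent dies of exhaustion.
static MetabResult metabolize(double energy, double store, const Cfg& g) {
  MetabResult r;
  r.energy = energy - g.living;
  r.store = store;
  r.refill_food = 0.0;
  if (r.energy < g.refill_thr && store > 0) {
    double want = (g.Emax - r.energy) / g.f2e;
    double take = std::min(store, want);
    if (take > 0) {
      r.store = store - take;
      r.energy += take * g.f2e;
      r.refill_food = take;
    }
  }
  r.died = (r.energy <= 0);
  return r;
}

// ---------------------------------------------------------------------------
// exported single-operation kernels (unit-test surface; the run loop below
// calls the same static functions)

// [[Rcpp::export]]
List cpp_forage_eat(double frac, double food, double store, double energy,
                    List cfg) {
  Cfg g = parse_cfg(cfg);
  ForageResult r = forage_eat(frac, food, store, energy, g);
  return List::create(_["store"] = r.store, _["energy"] = r.energy,
                      _["food"] = r.food, _["denuded"] = r.denuded,
                      _["eaten"] = r.eaten, _["cap_loss"] = r.cap_loss);
}

// [[Rcpp::export]]
List cpp_metabolize(double energy, double store, List cfg) {
  Cfg g = parse_cfg(cfg);
  MetabResult r = metabolize(energy, store, g);
  return List::create(_["energy"] = r.energy, _["store"] = r.store,
                      _["refill_food"] = r.refill_food, _["died"] = r.died);
}

// [[Rcpp::export]]
NumericVector cpp_mutate(double value, int n, List cfg) {
  Cfg g = parse_cfg(cfg);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mutate_one(value, g);
  return out;
}

// ---------------------------------------------------------------------------
// full engine

struct Agent {
  int id, x, y;           // 0-based coords internally
  double frac, energy, store;
  int age;
  bool sharer, alive;
  std::vector<short> lb, ld;  // vicinity ledger ring buffers (adaptive only)
  int sum_b, sum_d;
};

struct EventRec { int x, y; bool birth; };

class Sim {
public:
  Cfg g;
  bool shock_on, sharing_on, adaptive_on, predators_on;
  int W, H, n_cells;
  std::vector<double> food;
  std::vector<char> denuded, predator;
  double regrowth;
  int tick;
  std::vector<Agent> pop;
  std::vector<std::vector<int>> occ;
  int next_id;
  std::vector<EventRec> prev_events, cur_events;

  // logs
  bool record_events;
  std::vector<int> ev_tick, ev_id, ev_parent, ev_cause, ev_x, ev_y, ev_type;
  std::vector<double> ev_frac;
  std::vector<int> sh_tick, sh_donor, sh_recip;
  std::vector<double> sh_amount;
  long cause_counts[5];
  int innovation_tick;
  bool extinct;
  int extinct_tick;

  // per-tick balance components
  double bal_e_start, bal_credit, bal_living, bal_birthcost, bal_caploss,
      bal_deathloss;

  inline int idx(int x, int y) const { return x + y * W; }
  inline int wrap_x(int x) const { return ((x % W) + W) % W; }
  inline int wrap_y(int y) const { return ((y % H) + H) % H; }

  void occ_remove(int cell, int ai) {
    std::vector<int>& v = occ[cell];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == ai) { v[k] = v.back(); v.pop_back(); return; }
  }

  void record_event(const Agent& a, bool birth, int cause, int parent) {
    cur_events.push_back({a.x, a.y, birth});
    if (!birth) cause_counts[cause]++;
    if (record_events) {
      ev_tick.push_back(tick);
      ev_id.push_back(a.id);
      ev_parent.push_back(parent);
      ev_type.push_back(birth ? 1 : 2);
      ev_cause.push_back(cause);
      ev_x.push_back(a.x + 1);
      ev_y.push_back(a.y + 1);
      ev_frac.push_back(a.frac);
    }
  }

  void kill(int ai, int cause) {
    Agent& a = pop[ai];
    a.alive = false;
    bal_deathloss += a.energy;
    occ_remove(idx(a.x, a.y), ai);
    record_event(a, false, cause, NA_INTEGER);
  }

  void init_from_cfg() {
    W = g.W; H = g.H; n_cells = W * H;
    food.assign(n_cells, 0.0);
    denuded.assign(n_cells, 0);
    predator.assign(n_cells, 0);
    regrowth = g.regrow_n;
    tick = 0;
    // predator patches: distinct cells via partial Fisher-Yates
    int n_pred = predators_on ? g.n_pred : 0;
    std::vector<int> perm(n_cells);
    for (int i = 0; i < n_cells; ++i) perm[i] = i;
    for (int i = 0; i < n_pred; ++i) {
      int j = i + runif_int(n_cells - i);
      std::swap(perm[i], perm[j]);
      predator[perm[i]] = 1;
    }
    // initial food: uniform integer on [f0_lo, f0_hi] for non-predator cells
    int lo = (int)std::lround(g.f0_lo), hi = (int)std::lround(g.f0_hi);
    for (int c = 0; c < n_cells; ++c)
      if (!predator[c]) food[c] = lo + runif_int(hi - lo + 1);
    // agents on uniformly chosen non-predator cells; gene uniform on the grid
    pop.clear();
    next_id = 1;
    for (int i = 0; i < g.init_pop; ++i) {
      Agent a;
      a.id = next_id++;
      do {
        a.x = runif_int(W);
        a.y = runif_int(H);
      } while (predator[idx(a.x, a.y)]);
      a.frac = grid_snap(runif_int(11) / 10.0);
      a.energy = g.e0_lo + unif_rand() * (g.e0_hi - g.e0_lo);
      a.store = 0.0;
      // spread initial ages so the founding population is not a single
      // cohort (a cohort start would silence births for repro_age_min ticks)
      a.age = runif_int(g.old_thr + 1);
      a.sharer = false;
      a.alive = true;
      a.sum_b = a.sum_d = 0;
      if (adaptive_on) {
        a.lb.assign(g.ledger_window, 0);
        a.ld.assign(g.ledger_window, 0);
      }
      pop.push_back(a);
    }
  }

  void init_from_state(const List& st) {
    List world = st["world"];
    NumericMatrix fm = world["food"];
    LogicalMatrix dm = world["denuded"];
    LogicalMatrix pm = world["predator"];
    W = fm.nrow(); H = fm.ncol(); n_cells = W * H;
    food.assign(n_cells, 0.0);
    denuded.assign(n_cells, 0);
    predator.assign(n_cells, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        food[idx(x, y)] = fm(x, y);
        denuded[idx(x, y)] = dm(x, y);
        predator[idx(x, y)] = pm(x, y);
      }
    regrowth = as<double>(world["regrowth"]);
    tick = as<int>(world["tick"]);
    List ag = st["agents"];
    IntegerVector id = ag["id"], ax = ag["x"], ay = ag["y"], age = ag["age"];
    NumericVector fr = ag["frac"], en = ag["energy"], stv = ag["store"];
    LogicalVector sh = ag["sharer"];
    bool has_ledger = ag.containsElementNamed("ledger_births");
    IntegerMatrix lbm, ldm;
    if (has_ledger) {
      lbm = as<IntegerMatrix>(ag["ledger_births"]);
      ldm = as<IntegerMatrix>(ag["ledger_deaths"]);
    }
    pop.clear();
    next_id = 1;
    for (int i = 0; i < id.size(); ++i) {
      Agent a;
      a.id = id[i];
      if (a.id >= next_id) next_id = a.id + 1;
      a.x = ax[i] - 1; a.y = ay[i] - 1;
      a.frac = grid_snap(fr[i]);
      a.energy = en[i]; a.store = stv[i];
      a.age = age[i];
      a.sharer = sh[i];
      a.alive = true;
      a.sum_b = a.sum_d = 0;
      if (adaptive_on) {
        a.lb.assign(g.ledger_window, 0);
        a.ld.assign(g.ledger_window, 0);
        if (has_ledger) {
          for (int k = 0; k < g.ledger_window; ++k) {
            a.lb[k] = (short)lbm(i, k);
            a.ld[k] = (short)ldm(i, k);
            a.sum_b += a.lb[k];
            a.sum_d += a.ld[k];
          }
        }
      }
      pop.push_back(a);
    }
  }

  void rebuild_occ() {
    occ.assign(n_cells, {});
    for (size_t i = 0; i < pop.size(); ++i)
      if (pop[i].alive) occ[idx(pop[i].x, pop[i].y)].push_back((int)i);
  }

  // push the previous tick's birth/death events into every agent's ring
  // buffer, sampled at the agent's current (start-of-tick) position
  void ledger_update() {
    int p = tick % g.ledger_window;
    for (size_t i = 0; i < pop.size(); ++i) {
      Agent& a = pop[i];
      if (!a.alive) continue;
      a.sum_b -= a.lb[p]; a.sum_d -= a.ld[p];
      a.lb[p] = 0; a.ld[p] = 0;
    }
    int r = g.vic_radius;
    for (const EventRec& e : prev_events) {
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          int cell = idx(wrap_x(e.x + dx), wrap_y(e.y + dy));
          for (int ai : occ[cell]) {
            Agent& a = pop[ai];
            if (e.birth) { a.lb[p]++; a.sum_b++; }
            else { a.ld[p]++; a.sum_d++; }
          }
        }
    }
  }

  void do_share(int ai) {
    Agent& a = pop[ai];
    if (a.store < g.share_store_frac * g.Smax - GRID_TOL) return;
    int r = g.share_radius;
    int best = -1;
    double best_e = 0.0;
    double thr = g.share_energy_mult * g.living;
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        int cell = idx(wrap_x(a.x + dx), wrap_y(a.y + dy));
        for (int bi : occ[cell]) {
          if (bi == ai) continue;
          Agent& b = pop[bi];
          if (b.energy < thr && b.store <= GRID_TOL) {
            if (best < 0 || b.energy < best_e ||
                (b.energy == best_e && b.id < pop[best].id)) {
              best = bi;
              best_e = b.energy;
            }
          }
        }
      }
    if (best < 0) return;
    Agent& b = pop[best];
    double amt = std::min(g.share_amount, a.store);
    if (amt <= 0) return;
    a.store -= amt;
    double gain = amt * g.f2e;
    double room = g.Emax - b.energy;
    if (gain > room) { bal_caploss += gain - room; gain = room; }
    bal_credit += amt * g.f2e;
    b.energy += gain;
    sh_tick.push_back(tick);
    sh_donor.push_back(a.id);
    sh_recip.push_back(b.id);
    sh_amount.push_back(amt);
  }

  void step_agents() {
    // innovation: sharing can dawn on one agent when nobody shares
    if (sharing_on) {
      bool any_sharer = false;
      std::vector<int> alive_idx;
      for (size_t i = 0; i < pop.size(); ++i)
        if (pop[i].alive) {
          alive_idx.push_back((int)i);
          if (pop[i].sharer) any_sharer = true;
        }
      if (!any_sharer && !alive_idx.empty() && unif_rand() < g.innov_p) {
        pop[alive_idx[runif_int((int)alive_idx.size())]].sharer = true;
        if (innovation_tick < 0) innovation_tick = tick;
      }
    }
    if (adaptive_on) ledger_update();

    // shuffled order over agents alive at tick start
    std::vector<int> order;
    for (size_t i = 0; i < pop.size(); ++i)
      if (pop[i].alive) order.push_back((int)i);
    for (int i = (int)order.size() - 1; i > 0; --i)
      std::swap(order[i], order[runif_int(i + 1)]);

    static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

    for (int ai : order) {
      Agent& a = pop[ai];
      if (!a.alive) continue;

      // move to a uniform Moore neighbour; predators kill before foraging
      int k = runif_int(8);
      int nx = wrap_x(a.x + DX[k]), ny = wrap_y(a.y + DY[k]);
      occ_remove(idx(a.x, a.y), ai);
      a.x = nx; a.y = ny;
      int cell = idx(nx, ny);
      if (predator[cell]) {
        a.alive = false;
        bal_deathloss += a.energy;
        record_event(a, false, 3, NA_INTEGER);
        continue;
      }
      occ[cell].push_back(ai);

      // forage and eat surplus
      if (!denuded[cell] && food[cell] > 0 && a.frac > 0) {
        ForageResult fr = forage_eat(a.frac, food[cell], a.store, a.energy, g);
        a.store = fr.store;
        a.energy = fr.energy;
        food[cell] = fr.food;
        if (fr.denuded) denuded[cell] = 1;
        bal_credit += fr.eaten * g.f2e;
        bal_caploss += fr.cap_loss;
      }

      // sharing happens before metabolism so a rescue can avert
      // same-tick exhaustion
      if (sharing_on && a.sharer) do_share(ai);

      // metabolism and store refill
      MetabResult mr = metabolize(a.energy, a.store, g);
      bal_living += g.living;
      bal_credit += mr.refill_food * g.f2e;
      a.energy = mr.energy;
      a.store = mr.store;
      if (mr.died) { kill(ai, 2); continue; }

      // within-lifetime adaptation from the vicinity ledger
      if (adaptive_on) {
        int skew = a.sum_b - a.sum_d;
        if (skew > g.skew_thr && a.frac > GRID_TOL)
          a.frac = grid_snap(a.frac - 0.1);
        else if (skew < -g.skew_thr && a.frac < 1.0 - GRID_TOL)
          a.frac = grid_snap(a.frac + 0.1);
      }

      // reproduction
      if (a.age >= g.age_min && a.age <= g.age_max &&
          a.energy >= g.repro_frac * g.Emax) {
        a.energy -= g.birth_cost + g.birth_transfer;
        bal_birthcost += g.birth_cost;
        Agent ch;
        ch.id = next_id++;
        ch.x = a.x; ch.y = a.y;
        ch.frac = mutate_one(a.frac, g);
        ch.energy = g.birth_transfer;
        ch.store = 0.0;
        ch.age = 0;
        ch.sharer = a.sharer;  // vertical cultural transmission
        ch.alive = true;
        ch.sum_b = ch.sum_d = 0;
        if (adaptive_on) {
          ch.lb.assign(g.ledger_window, 0);
          ch.ld.assign(g.ledger_window, 0);
        }
        int parent_id = a.id;
        pop.push_back(ch);
        occ[idx(ch.x, ch.y)].push_back((int)pop.size() - 1);
        record_event(pop.back(), true, 0, parent_id);
        Agent& a2 = pop[ai];  // reference may have moved on push_back
        if (a2.energy <= 0) { kill(ai, 4); continue; }
      }

      // old age
      Agent& a3 = pop[ai];
      if (a3.age > g.old_thr && unif_rand() < g.old_p) kill(ai, 1);
    }

    // completed ticks of life
    for (int ai : order)
      if (pop[ai].alive) pop[ai].age++;
  }

  void step_environment() {
    double rate = regrowth;
    for (int c = 0; c < n_cells; ++c) {
      if (predator[c]) continue;
      if (denuded[c]) {
        if (g.recov_p > 0 && unif_rand() < g.recov_p) denuded[c] = 0;
      } else if (food[c] < g.Fmax) {
        food[c] = std::min(g.Fmax, food[c] + rate);
      }
    }
  }

  void compact() {
    std::vector<Agent> np;
    np.reserve(pop.size());
    for (Agent& a : pop)
      if (a.alive) np.push_back(std::move(a));
    pop.swap(np);
    rebuild_occ();
  }
};

// [[Rcpp::export]]
List sim_run_cpp(List cfg, List flags, Nullable<List> state_, int n_ticks,
                 bool record_events, bool record_balance) {
  Sim s;
  s.g = parse_cfg(cfg);
  s.shock_on = as<bool>(flags["shock"]);
  s.sharing_on = as<bool>(flags["sharing"]);
  s.adaptive_on = as<bool>(flags["adaptive"]);
  s.predators_on = as<bool>(flags["predators"]);
  s.record_events = record_events;
  for (int i = 0; i < 5; ++i) s.cause_counts[i] = 0;
  s.innovation_tick = -1;
  s.extinct = false;
  s.extinct_tick = -1;

  if (state_.isNotNull()) s.init_from_state(List(state_));
  else s.init_from_cfg();
  s.rebuild_occ();

  // 9 fixed time-series columns + 11 foraging-fraction histogram bins
  NumericMatrix ts(n_ticks, 20);
  NumericMatrix bal(record_balance ? n_ticks : 0, 7);

  int first_tick = s.tick;
  for (int t = 0; t < n_ticks; ++t) {
    int row = t;
    if (s.extinct) {  // padded zero rows after extinction
      ts(row, 0) = s.tick;
      s.tick++;
      continue;
    }
    // regime: shocked regrowth from shock_tick onwards
    if (s.shock_on && s.tick >= s.g.shock_tick) s.regrowth = s.g.regrow_s;

    double e_start = 0;
    for (const Agent& a : s.pop)
      if (a.alive) e_start += a.energy;
    s.bal_e_start = e_start;
    s.bal_credit = s.bal_living = s.bal_birthcost = 0;
    s.bal_caploss = s.bal_deathloss = 0;
    size_t share_before = s.sh_tick.size();

    s.step_agents();
    s.step_environment();

    // end-of-tick statistics
    double e_end = 0, st_sum = 0;
    int alive = 0, sharers = 0, wb = 0;
    int hist[11] = {0};
    for (const Agent& a : s.pop) {
      if (!a.alive) continue;
      alive++;
      e_end += a.energy;
      st_sum += a.store;
      if (a.sharer) sharers++;
      if (a.energy >= s.g.wb_mult * s.g.living || a.store > GRID_TOL) wb++;
      int b = (int)std::lround(a.frac * 10.0);
      if (b >= 0 && b <= 10) hist[b]++;
    }
    double food_sum = 0;
    int n_nonpred = 0, n_denuded = 0;
    for (int c = 0; c < s.n_cells; ++c) {
      if (s.predator[c]) continue;
      n_nonpred++;
      food_sum += s.food[c];
      if (s.denuded[c]) n_denuded++;
    }
    ts(row, 0) = s.tick;
    ts(row, 1) = alive;
    ts(row, 2) = n_nonpred > 0 ? 1.0 - (double)n_denuded / n_nonpred : 0.0;
    ts(row, 3) = n_nonpred > 0 ? food_sum / n_nonpred : 0.0;
    ts(row, 4) = alive > 0 ? e_end / alive : 0.0;
    ts(row, 5) = alive > 0 ? st_sum / alive : 0.0;
    ts(row, 6) = sharers;
    ts(row, 7) = (double)(s.sh_tick.size() - share_before);
    ts(row, 8) = wb;
    for (int b = 0; b <= 10; ++b) ts(row, 9 + b) = hist[b];

    if (record_balance) {
      bal(row, 0) = s.bal_e_start;
      bal(row, 1) = e_end;
      bal(row, 2) = s.bal_credit;
      bal(row, 3) = s.bal_living;
      bal(row, 4) = s.bal_birthcost;
      bal(row, 5) = s.bal_caploss;
      bal(row, 6) = s.bal_deathloss;
    }

    s.prev_events.swap(s.cur_events);
    s.cur_events.clear();
    s.tick++;
    s.compact();
    if (alive == 0) {
      s.extinct = true;
      s.extinct_tick = s.tick - 1;
    }
  }

  // final state back to R (1-based coordinates)
  int n = (int)s.pop.size();
  IntegerVector id(n), ax(n), ay(n), age(n);
  NumericVector fr(n), en(n), stv(n);
  LogicalVector sh(n);
  for (int i = 0; i < n; ++i) {
    const Agent& a = s.pop[i];
    id[i] = a.id; ax[i] = a.x + 1; ay[i] = a.y + 1;
    fr[i] = a.frac; en[i] = a.energy; stv[i] = a.store;
    age[i] = a.age; sh[i] = a.sharer;
  }
  List agents = List::create(
      _["id"] = id, _["x"] = ax, _["y"] = ay, _["frac"] = fr,
      _["energy"] = en, _["store"] = stv, _["age"] = age, _["sharer"] = sh);
  if (s.adaptive_on && n > 0) {
    IntegerMatrix lbm(n, s.g.ledger_window), ldm(n, s.g.ledger_window);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < s.g.ledger_window; ++k) {
        lbm(i, k) = s.pop[i].lb[k];
        ldm(i, k) = s.pop[i].ld[k];
      }
    agents["ledger_births"] = lbm;
    agents["ledger_deaths"] = ldm;
  }
  NumericMatrix fm(s.W, s.H);
  LogicalMatrix dm(s.W, s.H), pm(s.W, s.H);
  for (int y = 0; y < s.H; ++y)
    for (int x = 0; x < s.W; ++x) {
      fm(x, y) = s.food[s.idx(x, y)];
      dm(x, y) = s.denuded[s.idx(x, y)] != 0;
      pm(x, y) = s.predator[s.idx(x, y)] != 0;
    }
  List world = List::create(_["food"] = fm, _["denuded"] = dm,
                            _["predator"] = pm, _["regrowth"] = s.regrowth,
                            _["tick"] = s.tick);

  List events = List::create(
      _["tick"] = wrap(s.ev_tick), _["id"] = wrap(s.ev_id),
      _["parent"] = wrap(s.ev_parent), _["type"] = wrap(s.ev_type),
      _["cause"] = wrap(s.ev_cause), _["x"] = wrap(s.ev_x),
      _["y"] = wrap(s.ev_y), _["frac"] = wrap(s.ev_frac));
  List sharing = List::create(
      _["tick"] = wrap(s.sh_tick), _["donor"] = wrap(s.sh_donor),
      _["recipient"] = wrap(s.sh_recip), _["amount"] = wrap(s.sh_amount));
  IntegerVector causes = IntegerVector::create(
      _["OLD_AGE"] = (int)s.cause_counts[1],
      _["EXHAUSTION"] = (int)s.cause_counts[2],
      _["PREDATION"] = (int)s.cause_counts[3],
      _["BIRTH"] = (int)s.cause_counts[4]);

  return List::create(
      _["world"] = world, _["agents"] = agents, _["timeseries"] = ts,
      _["balance"] = bal, _["events"] = events, _["sharing"] = sharing,
      _["cause_counts"] = causes,
      _["n_sharing_events"] = (int)s.sh_tick.size(),
      _["innovation_tick"] = s.innovation_tick,
      _["extinct"] = s.extinct, _["extinct_tick"] = s.extinct_tick,
      _["first_tick"] = first_tick);
}
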