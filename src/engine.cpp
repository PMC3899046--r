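// Fiber-walk engine: growing self-avoiding walks on d-dimensional hypercubic
// lattices with optional lateral contraction (vertex merges) at every
// elongation step.  The lattice is materialized lazily around the walk; all
// vertex positions stay on the original integer grid (merges absorb vertices,
// they never move positions).  Undo records make backtracking restarts and
// bit-exact state restoration possible.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int MAXD = 5;     // dimensions 2..5 supported
static const int COORD_BITS = 12;  // signed coordinate range +/- 2047
static const int COORD_OFF = 1 << (COORD_BITS - 1);
static const int MAX_STEPS_HARD = 1800;  // keeps coordinates inside key range

typedef int64_t Key;

struct Label {
  std::array<int8_t, MAXD> e;
  Label() { e.fill(0); }
  bool operator==(const Label& o) const { return e == o.e; }
};

static inline int8_t clamp_sum(int a, int b) {
  int s = a + b;
  return (int8_t)(s > 0 ? 1 : (s < 0 ? -1 : 0));
}

struct Edge {
  int a, b;        // vertex ids; label is the direction a -> b
  Label lab;
  double len;
  int ccount;      // number of contractions causing this edge to exist
  bool sa;         // blocked for growth: self-avoiding or fiber edge
  bool in_fiber;
  bool alive;
};

struct Vertex {
  std::array<int, MAXD> pos;
  std::vector<int> inc;        // incident alive edge ids
  std::vector<Key> merged_from;
  bool alive;
  bool in_fiber;
  bool materialized;           // all 2d unit neighbours ensured
};

struct MergeLogEntry {
  int step;        // 1-based step index that triggered the merge
  int kept;        // vertex id
  Key removed;     // original coordinate of the absorbed vertex
  double via_len;
  // inherited edges, flattened
  std::vector<Key> inh_to;
  std::vector<Label> inh_lab;
  std::vector<double> inh_len;
  std::vector<int> inh_cc;
};

struct UndoRec {
  size_t nV, nE;
  std::vector<std::pair<int, Vertex> > vMod;
  std::vector<std::pair<int, Edge> > eMod;
  std::vector<std::pair<Key, int> > coordOld;
  std::vector<Key> coordNew;
  Label g_old;
  bool has_g_old;
  size_t fibLen, mergeLogLen, stepLogLen, mergeCountLen;
};

class Engine {
 public:
  int d;
  bool contract_on_step;
  bool log_events;
  bool record_undo;

  std::vector<Vertex> V;
  std::vector<Edge> E;
  std::unordered_map<Key, int> coord;

  std::vector<int> fib;          // vertex ids, origin first
  std::vector<int> fib_edges;    // edge ids
  std::vector<double> step_len;
  std::vector<int> merge_count;  // merges per step
  Label g;
  bool has_g;

  std::vector<Key> step_targets;          // event log: chosen target per step
  std::vector<MergeLogEntry> merge_log;   // event log: merges
  std::vector<UndoRec> undo_stack;

  long n_backtracks, n_restarts;

  Engine(int d_, bool fiber_mode, bool log_ev, bool rec_undo)
      : d(d_), contract_on_step(fiber_mode), log_events(log_ev),
        record_undo(rec_undo), has_g(false), n_backtracks(0), n_restarts(0),
        cur_undo(nullptr) {
    if (d < 2 || d > MAXD) stop("invalid-configuration: dimension must be in 2..%d", MAXD);
    init_origin();
  }

  void init_origin() {
    std::array<int, MAXD> o;
    o.fill(0);
    int v = new_vertex(o);
    V[v].in_fiber = true;
    fib.push_back(v);
    materialize(v);
  }

  void reset() {
    V.clear(); E.clear(); coord.clear();
    fib.clear(); fib_edges.clear(); step_len.clear(); merge_count.clear();
    step_targets.clear(); merge_log.clear(); undo_stack.clear();
    has_g = false;
    cur_undo = nullptr;
    init_origin();
  }

  // ---- basic helpers -----------------------------------------------------

  Key key_of(const std::array<int, MAXD>& p) const {
    Key k = 0;
    for (int i = 0; i < d; ++i) {
      int c = p[i] + COORD_OFF;
      if (c < 0 || c >= (1 << COORD_BITS)) stop("coordinate out of engine range");
      k = (k << COORD_BITS) | (Key)c;
    }
    return k;
  }

  std::array<int, MAXD> pos_of_key(Key k) const {
    std::array<int, MAXD> p;
    p.fill(0);
    for (int i = d - 1; i >= 0; --i) {
      p[i] = (int)(k & ((1 << COORD_BITS) - 1)) - COORD_OFF;
      k >>= COORD_BITS;
    }
    return p;
  }

  double dist(int u, int w) const {
    double s = 0;
    for (int i = 0; i < d; ++i) {
      double dx = V[u].pos[i] - V[w].pos[i];
      s += dx * dx;
    }
    return std::sqrt(s);
  }

  Label fwd_label(const Edge& e, int from) const {
    if (e.a == from) return e.lab;
    Label l;
    for (int i = 0; i < d; ++i) l.e[i] = -e.lab.e[i];
    return l;
  }

  int other(const Edge& e, int v) const { return e.a == v ? e.b : e.a; }

  int tip() const { return fib.back(); }
  int n_steps() const { return (int)fib.size() - 1; }

  // ---- undo bookkeeping --------------------------------------------------

  UndoRec* cur_undo;

  void save_vertex(int id) {
    if (!record_undo || cur_undo == nullptr) return;
    if ((size_t)id >= cur_undo->nV) return;  // created this step
    for (size_t i = 0; i < cur_undo->vMod.size(); ++i)
      if (cur_undo->vMod[i].first == id) return;
    cur_undo->vMod.push_back(std::make_pair(id, V[id]));
  }
  void save_edge(int id) {
    if (!record_undo || cur_undo == nullptr) return;
    if ((size_t)id >= cur_undo->nE) return;
    for (size_t i = 0; i < cur_undo->eMod.size(); ++i)
      if (cur_undo->eMod[i].first == id) return;
    cur_undo->eMod.push_back(std::make_pair(id, E[id]));
  }
  void note_coord_insert(Key k) {
    if (record_undo && cur_undo != nullptr) cur_undo->coordNew.push_back(k);
  }
  void note_coord_overwrite(Key k, int old) {
    if (record_undo && cur_undo != nullptr) {
      for (size_t i = 0; i < cur_undo->coordNew.size(); ++i)
        if (cur_undo->coordNew[i] == k) return;  // inserted this step
      for (size_t i = 0; i < cur_undo->coordOld.size(); ++i)
        if (cur_undo->coordOld[i].first == k) return;
      cur_undo->coordOld.push_back(std::make_pair(k, old));
    }
  }

  // ---- lattice materialization -------------------------------------------

  int new_vertex(const std::array<int, MAXD>& p) {
    Vertex v;
    v.pos = p;
    v.alive = true;
    v.in_fiber = false;
    v.materialized = false;
    V.push_back(v);
    int id = (int)V.size() - 1;
    Key k = key_of(p);
    coord[k] = id;
    note_coord_insert(k);
    return id;
  }

  int new_edge(int a, int b, const Label& lab, double len, int cc, bool sa) {
    Edge e;
    e.a = a; e.b = b; e.lab = lab; e.len = len; e.ccount = cc;
    e.sa = sa; e.in_fiber = false; e.alive = true;
    E.push_back(e);
    int id = (int)E.size() - 1;
    save_vertex(a); save_vertex(b);
    V[a].inc.push_back(id);
    V[b].inc.push_back(id);
    return id;
  }

  int edge_between(int u, int w) const {
    const std::vector<int>& inc = V[u].inc.size() <= V[w].inc.size() ? V[u].inc : V[w].inc;
    int v0 = V[u].inc.size() <= V[w].inc.size() ? u : w;
    int v1 = v0 == u ? w : u;
    for (size_t i = 0; i < inc.size(); ++i) {
      const Edge& e = E[inc[i]];
      if (e.alive && other(e, v0) == v1) return inc[i];
    }
    return -1;
  }

  // Ensure all 2d unit neighbours of v exist with their unit edges.
  void materialize(int v) {
    if (V[v].materialized) return;
    save_vertex(v);
    V[v].materialized = true;
    for (int ax = 0; ax < d; ++ax) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        std::array<int, MAXD> q = V[v].pos;
        q[ax] += sgn;
        Key k = key_of(q);
        std::unordered_map<Key, int>::iterator it = coord.find(k);
        if (it == coord.end()) {
          int w = new_vertex(q);
          Label lab;
          lab.e[ax] = (int8_t)sgn;
          new_edge(v, w, lab, 1.0, 0, false);
        } else {
          int w = it->second;
          if (w == v) continue;  // coordinate absorbed into v itself
          if (V[w].pos == q) {
            // plain vertex at its own coordinate: add missing unit edge
            if (edge_between(v, w) < 0) {
              Label lab;
              lab.e[ax] = (int8_t)sgn;
              new_edge(v, w, lab, 1.0, 0, false);
            }
          }
          // else: coordinate was absorbed into w; the inherited edge v-w was
          // created at merge time (the removed vertex's neighbourhood is
          // always materialized before merging), nothing to do.
        }
      }
    }
  }

  // ---- self-avoidance marking ---------------------------------------------

  void mark_sa_at(int v) {
    // every edge from v to a fiber vertex becomes self-avoiding
    for (size_t i = 0; i < V[v].inc.size(); ++i) {
      int eid = V[v].inc[i];
      Edge& e = E[eid];
      if (!e.alive || e.sa) continue;
      if (V[other(e, v)].in_fiber) {
        save_edge(eid);
        e.sa = true;
      }
    }
  }

  // ---- feasibility, lateral selection -------------------------------------

  static bool label_less(const Label& x, const Label& y, int d) {
    for (int i = 0; i < d; ++i) {
      if (x.e[i] != y.e[i]) return x.e[i] < y.e[i];
    }
    return false;
  }

  std::vector<int> sorted_by_label(const std::vector<int>& eids, int from) const {
    std::vector<std::pair<Label, int> > tmp;
    tmp.reserve(eids.size());
    for (size_t i = 0; i < eids.size(); ++i)
      tmp.push_back(std::make_pair(fwd_label(E[eids[i]], from), eids[i]));
    for (size_t i = 1; i < tmp.size(); ++i) {  // insertion sort, lists are tiny
      std::pair<Label, int> x = tmp[i];
      size_t j = i;
      while (j > 0 && label_less(x.first, tmp[j - 1].first, d)) {
        tmp[j] = tmp[j - 1];
        --j;
      }
      tmp[j] = x;
    }
    std::vector<int> out;
    out.reserve(tmp.size());
    for (size_t i = 0; i < tmp.size(); ++i) out.push_back(tmp[i].second);
    return out;
  }

  // The tip is always materialized and its self-avoiding edges marked by the
  // time this is called (init_origin / step_along take care of it), so the
  // query is non-mutating and safe to call outside an undo record.
  std::vector<int> feasible_edges() const {
    int t = tip();
    std::vector<int> out;
    for (size_t i = 0; i < V[t].inc.size(); ++i) {
      const Edge& e = E[V[t].inc[i]];
      if (e.alive && !e.sa && !V[other(e, t)].in_fiber) out.push_back(V[t].inc[i]);
    }
    return sorted_by_label(out, t);
  }

  // Lateral-selection rule at the current tip: outgoing non-self-avoiding
  // edges whose label has no entry opposite in sign to a nonzero entry of the
  // incoming growth label, and whose label differs from the growth label.
  std::vector<int> select_lateral() const {
    std::vector<int> out;
    if (!has_g) return out;
    int t = tip();
    for (size_t i = 0; i < V[t].inc.size(); ++i) {
      int eid = V[t].inc[i];
      const Edge& e = E[eid];
      if (!e.alive || e.sa) continue;
      Label l = fwd_label(e, t);
      if (l == g) continue;
      bool ok = true;
      for (int k = 0; k < d; ++k) {
        if (g.e[k] != 0 && l.e[k] == -g.e[k]) { ok = false; break; }
      }
      if (ok) out.push_back(eid);
    }
    return sorted_by_label(out, t);
  }

  // ---- merge (contraction) -------------------------------------------------

  void merge_via(int eid) {
    int t = tip();
    Edge& via = E[eid];
    if (!via.alive) stop("contract-forbidden: merge edge no longer exists");
    if (via.sa) stop("contract-forbidden: merge edge is self-avoiding");
    int u = other(via, t);
    if (V[u].in_fiber) stop("contract-forbidden: cannot absorb a fiber vertex");
    Label m = fwd_label(via, t);
    double via_len = via.len;

    materialize(u);  // inheritance must see the full original neighbourhood

    MergeLogEntry ml;
    if (log_events) {
      ml.step = n_steps();
      ml.kept = t;
      ml.removed = key_of(V[u].pos);
      ml.via_len = via_len;
    }

    save_vertex(u);
    save_vertex(t);
    std::vector<int> uinc = V[u].inc;  // copy: we modify as we go
    for (size_t i = 0; i < uinc.size(); ++i) {
      int fid = uinc[i];
      if (fid == eid) continue;
      Edge& f = E[fid];
      if (!f.alive) continue;
      int z = other(f, u);
      Label luz = fwd_label(f, u);
      Label nl;
      for (int k = 0; k < d; ++k) nl.e[k] = clamp_sum(m.e[k], luz.e[k]);
      double nlen = dist(t, z);
      int ncc = f.ccount + 1;
      bool nsa = f.sa || V[z].in_fiber;

      // detach f from z and drop it
      save_edge(fid);
      save_vertex(z);
      f.alive = false;
      drop_incidence(z, fid);

      int ex = edge_between(t, z);
      if (ex >= 0) {
        // parallel edge collision: keep one, larger contraction count wins
        Edge& x = E[ex];
        save_edge(ex);
        if (ncc > x.ccount) {
          x.ccount = ncc;
          x.lab = (x.a == t) ? nl : negate(nl);
        }
        x.sa = x.sa || nsa;
      } else {
        new_edge(t, z, nl, nlen, ncc, nsa);
      }
      if (log_events) {
        ml.inh_to.push_back(key_of(V[z].pos));
        ml.inh_lab.push_back(nl);
        ml.inh_len.push_back(nlen);
        ml.inh_cc.push_back(ncc);
      }
    }

    // discard the merge edge and the vertex (re-index E: new_edge calls above
    // may have reallocated the edge vector, invalidating `via`)
    E[eid].alive = false;
    drop_incidence(t, eid);
    V[u].inc.clear();
    V[u].alive = false;
    Key uk = key_of(V[u].pos);
    note_coord_overwrite(uk, u);
    coord[uk] = t;
    V[t].merged_from.push_back(uk);

    if (log_events) merge_log.push_back(ml);
  }

  Label negate(const Label& l) const {
    Label o;
    for (int i = 0; i < d; ++i) o.e[i] = -l.e[i];
    return o;
  }

  void drop_incidence(int v, int eid) {
    std::vector<int>& inc = V[v].inc;
    for (size_t i = 0; i < inc.size(); ++i) {
      if (inc[i] == eid) {
        inc.erase(inc.begin() + i);
        return;
      }
    }
  }

  int contract() {
    std::vector<int> sel = select_lateral();
    int n = 0;
    for (size_t i = 0; i < sel.size(); ++i) {
      const Edge& e = E[sel[i]];
      if (!e.alive || e.sa) continue;  // may change during earlier merges
      merge_via(sel[i]);
      ++n;
    }
    return n;
  }

  // ---- stepping -------------------------------------------------------------

  void begin_step() {
    if (record_undo) {
      UndoRec r;
      r.nV = V.size();
      r.nE = E.size();
      r.g_old = g;
      r.has_g_old = has_g;
      r.fibLen = fib.size();
      r.mergeLogLen = merge_log.size();
      r.stepLogLen = step_targets.size();
      r.mergeCountLen = merge_count.size();
      undo_stack.push_back(r);
      cur_undo = &undo_stack.back();
    } else {
      cur_undo = nullptr;
    }
  }

  // step along edge eid (must be feasible); applies contraction in fiber mode
  void step_along(int eid) {
    int t = tip();
    begin_step();
    Edge& e = E[eid];
    int w = other(e, t);
    Label lab = fwd_label(e, t);
    save_edge(eid);
    e.in_fiber = true;
    e.sa = true;
    save_vertex(w);
    V[w].in_fiber = true;
    fib.push_back(w);
    fib_edges.push_back(eid);
    step_len.push_back(e.len);
    g = lab;
    has_g = true;
    step_targets.push_back(key_of(V[w].pos));
    materialize(w);
    mark_sa_at(w);
    int nm = 0;
    if (contract_on_step) nm = contract();
    merge_count.push_back(nm);
    cur_undo = nullptr;
  }

  int step_random() {
    std::vector<int> feas = feasible_edges();
    if (feas.empty()) stop("illegal-state: walk is stopped");
    int i = (int)std::floor(unif_rand() * feas.size());
    if (i >= (int)feas.size()) i = (int)feas.size() - 1;
    step_along(feas[i]);
    return feas[i];
  }

  // step to the neighbour at the given coordinate (no RNG consumed)
  void step_to(const std::array<int, MAXD>& q) {
    std::vector<int> feas = feasible_edges();
    Key k = key_of(q);
    for (size_t i = 0; i < feas.size(); ++i) {
      int w = other(E[feas[i]], tip());
      if (key_of(V[w].pos) == k) {
        step_along(feas[i]);
        return;
      }
    }
    stop("invalid-edge: target is not a feasible neighbour of the tip");
  }

  bool undo() {
    if (undo_stack.empty()) return false;
    UndoRec& r = undo_stack.back();
    // remove coord entries inserted this step
    for (size_t i = 0; i < r.coordNew.size(); ++i) coord.erase(r.coordNew[i]);
    for (size_t i = 0; i < r.coordOld.size(); ++i)
      coord[r.coordOld[i].first] = r.coordOld[i].second;
    for (size_t i = 0; i < r.eMod.size(); ++i) E[r.eMod[i].first] = r.eMod[i].second;
    for (size_t i = 0; i < r.vMod.size(); ++i) V[r.vMod[i].first] = r.vMod[i].second;
    V.resize(r.nV);
    E.resize(r.nE);
    fib.resize(r.fibLen);
    fib_edges.resize(r.fibLen - 1);
    step_len.resize(r.fibLen - 1);
    merge_count.resize(r.mergeCountLen);
    merge_log.resize(r.mergeLogLen);
    step_targets.resize(r.stepLogLen);
    g = r.g_old;
    has_g = r.has_g_old;
    undo_stack.pop_back();
    return true;
  }

  bool stopped() { return feasible_edges().empty(); }

  // ---- full runs -------------------------------------------------------------

  // restart: 0 none, 1 backtrack, 2 rejection
  // returns 0 ok, 1 budget exhausted / unresolvable
  int run(int max_steps, int restart, long max_backtracks) {
    if (max_steps < 1 || max_steps > MAX_STEPS_HARD)
      stop("invalid-configuration: max_steps must be in 1..%d", MAX_STEPS_HARD);
    if (restart == 1 && !record_undo)
      stop("invalid-configuration: backtracking requires undo recording");
    const long bt0 = n_backtracks, rs0 = n_restarts;  // budget per run() call
    if (restart == 0) {
      while (n_steps() < max_steps) {
        std::vector<int> feas = feasible_edges();
        if (feas.empty()) return 0;
        int i = (int)std::floor(unif_rand() * feas.size());
        if (i >= (int)feas.size()) i = (int)feas.size() - 1;
        step_along(feas[i]);
      }
      return 0;
    }
    if (restart == 2) {
      while (true) {
        while (n_steps() < max_steps) {
          std::vector<int> feas = feasible_edges();
          if (feas.empty()) break;
          int i = (int)std::floor(unif_rand() * feas.size());
          if (i >= (int)feas.size()) i = (int)feas.size() - 1;
          step_along(feas[i]);
        }
        if (n_steps() >= max_steps) return 0;
        ++n_restarts;
        if (n_restarts - rs0 > max_backtracks) return 1;
        reset();
      }
    }
    // backtrack: depth-first with per-depth exclusion sets
    std::vector<std::vector<Key> > excl(max_steps + 1);
    while (n_steps() < max_steps) {
      std::vector<int> feas = feasible_edges();
      std::vector<int> open;
      std::vector<Key>& ex = excl[n_steps()];
      for (size_t i = 0; i < feas.size(); ++i) {
        Key k = key_of(V[other(E[feas[i]], tip())].pos);
        bool excluded = false;
        for (size_t j = 0; j < ex.size(); ++j)
          if (ex[j] == k) { excluded = true; break; }
        if (!excluded) open.push_back(feas[i]);
      }
      if (open.empty()) {
        if (n_steps() == 0) return 1;  // exhausted back to the origin
        ex.clear();
        Key undone = step_targets.back();
        if (!undo()) return 1;
        excl[n_steps()].push_back(undone);
        ++n_backtracks;
        if (n_backtracks - bt0 > max_backtracks) return 1;
        continue;
      }
      int i = (int)std::floor(unif_rand() * open.size());
      if (i >= (int)open.size()) i = (int)open.size() - 1;
      step_along(open[i]);
    }
    return 0;
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static Engine* get(SEXP xp) {
  XPtr<Engine> p(xp);
  if (!p) stop("invalid engine pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP fw_new(int dimension, bool fiber_mode, bool log_events, bool record_undo) {
  XPtr<Engine> p(new Engine(dimension, fiber_mode, log_events, record_undo), true);
  return p;
}

// [[Rcpp::export]]
int fw_dim(SEXP xp) { return get(xp)->d; }

// [[Rcpp::export]]
int fw_n_steps(SEXP xp) { return get(xp)->n_steps(); }

// [[Rcpp::export]]
bool fw_stopped(SEXP xp) { return get(xp)->stopped(); }

// [[Rcpp::export]]
bool fw_is_fiber_mode(SEXP xp) { return get(xp)->contract_on_step; }

static IntegerMatrix positions_of(Engine* en, const std::vector<int>& ids) {
  IntegerMatrix m(ids.size(), en->d);
  for (size_t i = 0; i < ids.size(); ++i)
    for (int j = 0; j < en->d; ++j) m(i, j) = en->V[ids[i]].pos[j];
  return m;
}

static List edge_view(Engine* en, const std::vector<int>& eids, int from) {
  int n = (int)eids.size();
  IntegerMatrix tgt(n, en->d);
  IntegerMatrix lab(n, en->d);
  NumericVector len(n);
  IntegerVector cc(n);
  LogicalVector sa(n);
  for (int i = 0; i < n; ++i) {
    const Edge& e = en->E[eids[i]];
    int w = en->other(e, from);
    Label l = en->fwd_label(e, from);
    for (int j = 0; j < en->d; ++j) {
      tgt(i, j) = en->V[w].pos[j];
      lab(i, j) = l.e[j];
    }
    len[i] = e.len;
    cc[i] = e.ccount;
    sa[i] = e.sa;
  }
  return List::create(_["target"] = tgt, _["label"] = lab, _["length"] = len,
                      _["contraction_count"] = cc, _["self_avoiding"] = sa);
}

// [[Rcpp::export]]
List fw_feasible(SEXP xp) {
  Engine* en = get(xp);
  std::vector<int> f = en->feasible_edges();
  return edge_view(en, f, en->tip());
}

// [[Rcpp::export]]
List fw_lateral(SEXP xp) {
  Engine* en = get(xp);
  std::vector<int> f = en->select_lateral();
  return edge_view(en, f, en->tip());
}

// [[Rcpp::export]]
List fw_incident(SEXP xp, IntegerVector pos) {
  Engine* en = get(xp);
  if (pos.size() != en->d) stop("lookup error: position has wrong dimension");
  std::array<int, MAXD> p;
  p.fill(0);
  for (int i = 0; i < en->d; ++i) p[i] = pos[i];
  std::unordered_map<Key, int>::iterator it = en->coord.find(en->key_of(p));
  if (it == en->coord.end()) stop("lookup error: unknown vertex");
  int v = it->second;
  // attribute on-demand materialization to the most recent undo record so a
  // later undo removes it consistently
  if (en->record_undo && !en->undo_stack.empty())
    en->cur_undo = &en->undo_stack.back();
  en->materialize(v);
  en->cur_undo = nullptr;
  std::vector<int> eids;
  for (size_t i = 0; i < en->V[v].inc.size(); ++i)
    if (en->E[en->V[v].inc[i]].alive) eids.push_back(en->V[v].inc[i]);
  eids = en->sorted_by_label(eids, v);
  return edge_view(en, eids, v);
}

// [[Rcpp::export]]
List fw_step_random(SEXP xp) {
  Engine* en = get(xp);
  int before = en->merge_log.empty() ? 0 : (int)en->merge_log.size();
  en->step_random();
  return List::create(_["step"] = en->n_steps(),
                      _["length"] = en->step_len.back(),
                      _["n_merges"] = en->merge_count.back(),
                      _["merge_log_from"] = before + 1);
}

// [[Rcpp::export]]
List fw_step_to(SEXP xp, IntegerVector target) {
  Engine* en = get(xp);
  if (target.size() != en->d) stop("invalid-edge: target has wrong dimension");
  std::array<int, MAXD> q;
  q.fill(0);
  for (int i = 0; i < en->d; ++i) q[i] = target[i];
  en->step_to(q);
  return List::create(_["step"] = en->n_steps(),
                      _["length"] = en->step_len.back(),
                      _["n_merges"] = en->merge_count.back());
}

// Apply the contraction rule manually at the current tip (outside fiber mode
// this lets a growing-SAW state be contracted step by step for inspection).
// Changes are attributed to the most recent step's undo record.
// [[Rcpp::export]]
int fw_contract(SEXP xp) {
  Engine* en = get(xp);
  if (!en->has_g) stop("illegal-state: no step has been taken yet");
  if (en->record_undo && !en->undo_stack.empty())
    en->cur_undo = &en->undo_stack.back();
  int n = en->contract();
  en->cur_undo = nullptr;
  return n;
}

// [[Rcpp::export]]
bool fw_undo(SEXP xp) { return get(xp)->undo(); }

// [[Rcpp::export]]
List fw_run(SEXP xp, int max_steps, int restart, double max_backtracks) {
  Engine* en = get(xp);
  int rc = en->run(max_steps, restart, (long)max_backtracks);
  return List::create(_["ok"] = (rc == 0), _["length"] = en->n_steps(),
                      _["stopped"] = en->stopped(),
                      _["n_backtracks"] = (double)en->n_backtracks,
                      _["n_restarts"] = (double)en->n_restarts);
}

// [[Rcpp::export]]
IntegerMatrix fw_positions(SEXP xp) {
  Engine* en = get(xp);
  return positions_of(en, en->fib);
}

// [[Rcpp::export]]
NumericVector fw_step_lengths(SEXP xp) {
  Engine* en = get(xp);
  return NumericVector(en->step_len.begin(), en->step_len.end());
}

// [[Rcpp::export]]
IntegerVector fw_merge_counts(SEXP xp) {
  Engine* en = get(xp);
  return IntegerVector(en->merge_count.begin(), en->merge_count.end());
}

// [[Rcpp::export]]
IntegerVector fw_last_label(SEXP xp) {
  Engine* en = get(xp);
  IntegerVector l(en->d);
  if (en->has_g)
    for (int i = 0; i < en->d; ++i) l[i] = en->g.e[i];
  else
    l.fill(NA_INTEGER);
  return l;
}

// squared edge lengths are integers on the integer grid; tally by them
static void tally(std::map<int, double>& m, double len) {
  int l2 = (int)std::lround(len * len);
  m[l2] += 1.0;
}

// [[Rcpp::export]]
List fw_edge_classes(SEXP xp) {
  Engine* en = get(xp);
  std::map<int, double> fibm, sam;
  for (size_t i = 0; i < en->E.size(); ++i) {
    const Edge& e = en->E[i];
    if (!e.alive) continue;
    if (e.in_fiber) tally(fibm, e.len);
    else if (e.sa) tally(sam, e.len);
  }
  IntegerVector fk, sk;
  NumericVector fc, sc;
  for (std::map<int, double>::iterator it = fibm.begin(); it != fibm.end(); ++it) {
    fk.push_back(it->first);
    fc.push_back(it->second);
  }
  for (std::map<int, double>::iterator it = sam.begin(); it != sam.end(); ++it) {
    sk.push_back(it->first);
    sc.push_back(it->second);
  }
  return List::create(
      _["fiber"] = List::create(_["length_sq"] = fk, _["count"] = fc),
      _["self_avoiding"] = List::create(_["length_sq"] = sk, _["count"] = sc));
}

// [[Rcpp::export]]
List fw_snapshot(SEXP xp, bool include_events) {
  Engine* en = get(xp);
  // vertices
  std::vector<int> alive;
  for (size_t i = 0; i < en->V.size(); ++i)
    if (en->V[i].alive) alive.push_back((int)i);
  IntegerMatrix vpos(alive.size(), en->d);
  LogicalVector vfib(alive.size());
  List mf(alive.size());
  IntegerVector vid(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) {
    const Vertex& v = en->V[alive[i]];
    vid[i] = alive[i];
    for (int j = 0; j < en->d; ++j) vpos(i, j) = v.pos[j];
    vfib[i] = v.in_fiber;
    IntegerMatrix mm(v.merged_from.size(), en->d);
    for (size_t r = 0; r < v.merged_from.size(); ++r) {
      std::array<int, MAXD> p = en->pos_of_key(v.merged_from[r]);
      for (int j = 0; j < en->d; ++j) mm(r, j) = p[j];
    }
    mf[i] = mm;
  }
  // edges
  std::vector<int> ae;
  for (size_t i = 0; i < en->E.size(); ++i)
    if (en->E[i].alive) ae.push_back((int)i);
  IntegerVector ea(ae.size()), eb(ae.size()), ecc(ae.size());
  IntegerMatrix elab(ae.size(), en->d);
  NumericVector elen(ae.size());
  LogicalVector esa(ae.size()), efib(ae.size());
  for (size_t i = 0; i < ae.size(); ++i) {
    const Edge& e = en->E[ae[i]];
    ea[i] = e.a;
    eb[i] = e.b;
    for (int j = 0; j < en->d; ++j) elab(i, j) = e.lab.e[j];
    elen[i] = e.len;
    ecc[i] = e.ccount;
    esa[i] = e.sa;
    efib[i] = e.in_fiber;
  }
  List out = List::create(
      _["dimension"] = en->d,
      _["mode"] = en->contract_on_step ? "fiber_walk" : "growing_saw",
      _["vertices"] = List::create(_["id"] = vid, _["position"] = vpos,
                                   _["in_fiber"] = vfib, _["merged_from"] = mf),
      _["edges"] = List::create(_["a"] = ea, _["b"] = eb, _["label"] = elab,
                                _["length"] = elen, _["contraction_count"] = ecc,
                                _["self_avoiding"] = esa, _["in_fiber"] = efib),
      _["fiber"] = List::create(_["vertex_id"] = IntegerVector(en->fib.begin(), en->fib.end()),
                                _["position"] = positions_of(en, en->fib),
                                _["step_length"] = NumericVector(en->step_len.begin(), en->step_len.end())),
      _["last_label"] = fw_last_label(xp),
      _["stopped"] = en->stopped());
  if (include_events) {
    int ns = (int)en->step_targets.size();
    IntegerMatrix st(ns, en->d);
    for (int i = 0; i < ns; ++i) {
      std::array<int, MAXD> p = en->pos_of_key(en->step_targets[i]);
      for (int j = 0; j < en->d; ++j) st(i, j) = p[j];
    }
    List merges(en->merge_log.size());
    for (size_t i = 0; i < en->merge_log.size(); ++i) {
      const MergeLogEntry& ml = en->merge_log[i];
      std::array<int, MAXD> rp = en->pos_of_key(ml.removed);
      IntegerVector rem(en->d);
      for (int j = 0; j < en->d; ++j) rem[j] = rp[j];
      int ni = (int)ml.inh_to.size();
      IntegerMatrix ito(ni, en->d), ilab(ni, en->d);
      NumericVector ilen(ni);
      IntegerVector icc(ni);
      for (int r = 0; r < ni; ++r) {
        std::array<int, MAXD> p = en->pos_of_key(ml.inh_to[r]);
        for (int j = 0; j < en->d; ++j) {
          ito(r, j) = p[j];
          ilab(r, j) = ml.inh_lab[r].e[j];
        }
        ilen[r] = ml.inh_len[r];
        icc[r] = ml.inh_cc[r];
      }
      merges[i] = List::create(
          _["step_index"] = ml.step, _["kept_vertex"] = ml.kept,
          _["removed_position"] = rem, _["via_length"] = ml.via_len,
          _["inherited_to"] = ito, _["inherited_label"] = ilab,
          _["inherited_length"] = ilen, _["inherited_contraction_count"] = icc);
    }
    out["events"] = List::create(_["step_targets"] = st, _["merges"] = merges,
                                 _["merge_count"] = fw_merge_counts(xp));
  }
  return out;
}

// ---------------------------------------------------------------------------
// ensemble driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fw_ensemble(int dimension, bool fiber_mode, int n_walks, int max_steps,
                 int restart, double max_backtracks, bool collect_disp,
                 bool collect_merges, bool collect_classes) {
  if (n_walks < 1) stop("invalid-configuration: n_walks must be >= 1");
  IntegerVector stop_len(n_walks);
  LogicalVector natural(n_walks);
  NumericMatrix disp;
  NumericMatrix merges;
  if (collect_disp) disp = NumericMatrix(n_walks, max_steps);
  if (collect_merges) merges = NumericMatrix(n_walks, max_steps);
  std::map<int, double> fibm, sam;
  double total_bt = 0, total_rs = 0;
  int n_failed = 0;

  for (int w = 0; w < n_walks; ++w) {
    Engine en(dimension, fiber_mode, false, restart == 1);
    int rc = en.run(max_steps, restart, (long)max_backtracks);
    if (rc != 0) {
      ++n_failed;
      // resample from the stream until a resolvable walk appears
      int tries = 0;
      while (rc != 0 && tries < 50) {
        en.reset();
        rc = en.run(max_steps, restart, (long)max_backtracks);
        ++tries;
      }
      if (rc != 0) stop("unresolvable-walk: backtracking budget exhausted repeatedly");
    }
    stop_len[w] = en.n_steps();
    natural[w] = en.stopped();
    total_bt += en.n_backtracks;
    total_rs += en.n_restarts;
    if (collect_disp) {
      int n = en.n_steps();
      for (int s = 0; s < max_steps; ++s) {
        if (s < n) {
          double sq = 0;
          const Vertex& o = en.V[en.fib[0]];
          const Vertex& t = en.V[en.fib[s + 1]];
          for (int j = 0; j < en.d; ++j) {
            double dx = t.pos[j] - o.pos[j];
            sq += dx * dx;
          }
          disp(w, s) = sq;
        } else {
          disp(w, s) = NA_REAL;
        }
      }
    }
    if (collect_merges) {
      double cum = 0;
      int n = (int)en.merge_count.size();
      for (int s = 0; s < max_steps; ++s) {
        if (s < n) {
          cum += en.merge_count[s];
          merges(w, s) = cum;
        } else {
          merges(w, s) = NA_REAL;
        }
      }
    }
    if (collect_classes) {
      for (size_t i = 0; i < en.E.size(); ++i) {
        const Edge& e = en.E[i];
        if (!e.alive) continue;
        if (e.in_fiber) tally(fibm, e.len);
        else if (e.sa) tally(sam, e.len);
      }
    }
    if ((w & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["stopping_length"] = stop_len, _["stopped_naturally"] = natural,
      _["n_backtracks"] = total_bt, _["n_restarts"] = total_rs,
      _["n_failed"] = n_failed);
  if (collect_disp) out["sq_displacement"] = disp;
  if (collect_merges) out["cum_merges"] = merges;
  if (collect_classes) {
    IntegerVector fk, sk;
    NumericVector fc, sc;
    for (std::map<int, double>::iterator it = fibm.begin(); it != fibm.end(); ++it) {
      fk.push_back(it->first);
      fc.push_back(it->second);
    }
    for (std::map<int, double>::iterator it = sam.begin(); it != sam.end(); ++it) {
      sk.push_back(it->first);
      sc.push_back(it->second);
    }
    out["fiber_classes"] = List::create(_["length_sq"] = fk, _["count"] = fc);
    out["sa_classes"] = List::create(_["length_sq"] = sk, _["count"] = sc);
  }
  return out;
}
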