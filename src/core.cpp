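// Simulation engine: gate semantics, genome decoding, synchronous brain
// updates, episode execution on the lattice task, the generational GA, and
// transition-matrix construction. All randomness uses R's RNG (unif_rand /
// rbinom) so set.seed() makes every entry point reproducible.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double P_MIN = 0.01;    // factor clamp after feedback
static const double DELTA_MAX = 0.5; // largest encodable feedback delta

// gate type ids (order matters: genome type locus indexes the enabled set)
enum GateType { GT_DET = 0, GT_PROB = 1, GT_DECOMP = 2, GT_DFB = 3, GT_FB = 4 };

struct Gate {
  int type = GT_DET;
  int ni = 1, no = 1;
  int in[4] = {0, 0, 0, 0};
  int out[4] = {0, 0, 0, 0};
  // current (learned) and birth (genome-encoded) tables; row-major,
  // 2^ni rows of 2^no entries. First listed node = most significant bit.
  std::vector<double> table, table0;
  // per-bit on-probabilities for decomposable types; 2^ni rows of no entries
  std::vector<double> factors, factors0;
  // feedback wiring (types GT_DFB, GT_FB)
  int pos_node = -1, neg_node = -1, hist_len = 0;
  double pos_delta[3] = {0, 0, 0}, neg_delta[3] = {0, 0, 0};
  // decision history ring, most recent first
  int hist_in[3] = {0, 0, 0}, hist_out[3] = {0, 0, 0}, hist_n = 0;
  // per-output-pattern OR masks over the node bit-vector (hot-loop cache)
  std::vector<uint32_t> wmask;

  bool feedback_capable() const { return type == GT_DFB || type == GT_FB; }
};

// node states live in one 32-bit word: node k = bit k (so <= 26 nodes)
struct Brain {
  int n = 16;
  int n_sensors = 4, n_motors = 2;
  bool learning = true;
  uint32_t state = 0;
  std::vector<Gate> gates;
};

static void build_wmask(Gate &g) {
  int nO = 1 << g.no;
  g.wmask.assign(nO, 0u);
  for (int p = 0; p < nO; ++p)
    for (int j = 0; j < g.no; ++j)
      if ((p >> (g.no - 1 - j)) & 1) g.wmask[p] |= 1u << g.out[j];
}

static void rebuild_row(Gate &g, int pat) {
  int nO = 1 << g.no;
  for (int p = 0; p < nO; ++p) {
    double pr = 1.0;
    for (int j = 0; j < g.no; ++j) {
      double f = g.factors[(size_t)pat * g.no + j];
      int bit = (p >> (g.no - 1 - j)) & 1;
      pr *= bit ? f : 1.0 - f;
    }
    g.table[(size_t)pat * nO + p] = pr;
  }
}

static void rebuild_all_rows(Gate &g) {
  for (int pat = 0; pat < (1 << g.ni); ++pat) rebuild_row(g, pat);
}

static inline double clamp_factor(double f) {
  if (f < P_MIN) return P_MIN;
  if (f > 1.0 - P_MIN) return 1.0 - P_MIN;
  return f;
}

// One gate firing: read input pattern from st, sample (or select) the output
// pattern, OR the set bits into nxt, and remember the decision for
// feedback-capable gates.
static inline void gate_fire(Gate &g, uint32_t st, uint32_t &nxt) {
  int pat = 0;
  for (int k = 0; k < g.ni; ++k) pat = (pat << 1) | ((st >> g.in[k]) & 1u);
  int nO = 1 << g.no;
  const double *row = &g.table[(size_t)pat * nO];
  int outp;
  if (g.type == GT_DET) { // unique 1.0 entry; consumes no randomness
    outp = 0;
    double best = -1.0;
    for (int p = 0; p < nO; ++p)
      if (row[p] > best) { best = row[p]; outp = p; }
  } else {
    double u = unif_rand(), c = 0.0;
    outp = nO - 1;
    for (int p = 0; p < nO; ++p) {
      c += row[p];
      if (u < c) { outp = p; break; }
    }
  }
  nxt |= g.wmask[outp];
  if (g.feedback_capable() && g.hist_len > 0) {
    int cap = g.hist_len;
    for (int d = std::min(g.hist_n, cap - 1); d > 0; --d) {
      g.hist_in[d] = g.hist_in[d - 1];
      g.hist_out[d] = g.hist_out[d - 1];
    }
    g.hist_in[0] = pat;
    g.hist_out[0] = outp;
    if (g.hist_n < cap) g.hist_n++;
  }
}

// Reinforce (positive) or punish (negative) every remembered decision.
// Decomposable feedback gates move each per-bit factor toward (away from)
// the emitted bit value and rebuild the affected row, so rows stay
// factorisable by construction. Legacy feedback gates shift row mass and
// renormalise.
static void gate_feedback(Gate &g, bool positive) {
  for (int d = 0; d < g.hist_n; ++d) {
    double delta = positive ? g.pos_delta[d] : g.neg_delta[d];
    int pat = g.hist_in[d], outp = g.hist_out[d];
    if (g.type == GT_DFB) {
      for (int j = 0; j < g.no; ++j) {
        int bit = (outp >> (g.no - 1 - j)) & 1;
        double &f = g.factors[(size_t)pat * g.no + j];
        double toward = bit ? delta : -delta;
        f = clamp_factor(f + (positive ? toward : -toward));
      }
      rebuild_row(g, pat);
    } else if (g.type == GT_FB) {
      int nO = 1 << g.no;
      if (nO < 2) continue;
      double *row = &g.table[(size_t)pat * nO];
      int other = (int)(unif_rand() * (nO - 1));
      if (other >= outp) other++;
      double s = positive ? delta : -delta;
      row[outp] += s;
      row[other] -= s;
      double tot = 0.0;
      for (int p = 0; p < nO; ++p) {
        if (row[p] < 0) row[p] = 0;
        if (row[p] > 1) row[p] = 1;
        tot += row[p];
      }
      if (tot <= 0)
        for (int p = 0; p < nO; ++p) row[p] = 1.0 / nO;
      else
        for (int p = 0; p < nO; ++p) row[p] /= tot;
    }
  }
}

// Synchronous, double-buffered update. Multiple writers OR; unwritten nodes
// fall back to 0. Feedback trigger nodes are read from the NEW state,
// positive before negative, gates in list order.
static void brain_step(Brain &b) {
  uint32_t nxt = 0;
  for (auto &g : b.gates) gate_fire(g, b.state, nxt);
  b.state = nxt;
  if (b.learning) {
    for (auto &g : b.gates) {
      if (!g.feedback_capable()) continue;
      if (g.pos_node >= 0 && ((b.state >> g.pos_node) & 1u))
        gate_feedback(g, true);
      if (g.neg_node >= 0 && ((b.state >> g.neg_node) & 1u))
        gate_feedback(g, false);
    }
  }
}

static void brain_reset_states(Brain &b) {
  b.state = 0;
  for (auto &g : b.gates) g.hist_n = 0;
}

static void brain_reset_learning(Brain &b) {
  for (auto &g : b.gates) {
    g.table = g.table0;
    g.factors = g.factors0;
    g.hist_n = 0;
  }
}

// ---------------------------------------------------------------------------
// Genome decoding
//
// Start codon: locus pair (42, 213). Gene body, fixed-width fields:
//   type locus (mod #enabled types), ni locus (1 + mod 4), no locus
//   (1 + mod 4), 4 input-address loci, 4 output-address loci (mod n_nodes;
//   first ni / no used), payload, and for feedback types a 9-locus block:
//   pos node, neg node, history length (mod 4), 3 positive + 3 negative
//   per-depth deltas (v/255 * DELTA_MAX).
// Payload: deterministic 2^ni loci (each mod 2^no = the chosen output);
// decomposable 2^ni*no factor loci (v/255); probabilistic/legacy-feedback
// 2^ni*2^no loci, rows normalised with +1 smoothing.
// ---------------------------------------------------------------------------

static const int CODON_A = 42, CODON_B = 213;

struct GeneLayout {
  int type, ni, no;
  int payload_len, fb_len, total_len; // total includes the 2 codon loci
};

static bool gene_layout(const std::vector<int> &g, size_t pos,
                        const std::vector<int> &enabled, GeneLayout &L) {
  size_t p = pos + 2;
  if (p + 3 > g.size()) return false;
  L.type = enabled[g[p] % enabled.size()];
  L.ni = 1 + (g[p + 1] % 4);
  L.no = 1 + (g[p + 2] % 4);
  p += 3 + 8; // addresses
  int rows = 1 << L.ni;
  switch (L.type) {
    case GT_DET: L.payload_len = rows; break;
    case GT_DECOMP:
    case GT_DFB: L.payload_len = rows * L.no; break;
    default: L.payload_len = rows * (1 << L.no); break;
  }
  L.fb_len = (L.type == GT_DFB || L.type == GT_FB) ? 9 : 0;
  L.total_len = 2 + 3 + 8 + L.payload_len + L.fb_len;
  return pos + (size_t)L.total_len <= g.size();
}

static bool decode_gene(const std::vector<int> &g, size_t pos, int n_nodes,
                        const std::vector<int> &enabled, Gate &gt) {
  GeneLayout L;
  if (!gene_layout(g, pos, enabled, L)) return false;
  gt = Gate();
  gt.type = L.type;
  gt.ni = L.ni;
  gt.no = L.no;
  size_t p = pos + 5;
  for (int k = 0; k < 4; ++k) gt.in[k] = g[p + k] % n_nodes;
  p += 4;
  for (int k = 0; k < 4; ++k) gt.out[k] = g[p + k] % n_nodes;
  p += 4;
  int rows = 1 << gt.ni, nO = 1 << gt.no;
  gt.table.assign((size_t)rows * nO, 0.0);
  if (gt.type == GT_DET) {
    for (int r = 0; r < rows; ++r)
      gt.table[(size_t)r * nO + (g[p + r] % nO)] = 1.0;
    p += rows;
  } else if (gt.type == GT_DECOMP || gt.type == GT_DFB) {
    gt.factors.assign((size_t)rows * gt.no, 0.0);
    for (int r = 0; r < rows; ++r)
      for (int j = 0; j < gt.no; ++j)
        gt.factors[(size_t)r * gt.no + j] = g[p + r * gt.no + j] / 255.0;
    p += (size_t)rows * gt.no;
    rebuild_all_rows(gt);
  } else {
    for (int r = 0; r < rows; ++r) {
      double tot = 0.0;
      for (int c = 0; c < nO; ++c) tot += g[p + r * nO + c] + 1.0;
      for (int c = 0; c < nO; ++c)
        gt.table[(size_t)r * nO + c] = (g[p + r * nO + c] + 1.0) / tot;
    }
    p += (size_t)rows * nO;
  }
  if (L.fb_len > 0) {
    gt.pos_node = g[p] % n_nodes;
    gt.neg_node = g[p + 1] % n_nodes;
    gt.hist_len = g[p + 2] % 4;
    for (int d = 0; d < 3; ++d) {
      gt.pos_delta[d] = g[p + 3 + d] / 255.0 * DELTA_MAX;
      gt.neg_delta[d] = g[p + 6 + d] / 255.0 * DELTA_MAX;
    }
  }
  gt.table0 = gt.table;
  gt.factors0 = gt.factors;
  build_wmask(gt);
  return true;
}

static Brain decode_brain(const std::vector<int> &genome, int n_nodes,
                          const std::vector<int> &enabled, bool learning) {
  Brain b;
  b.n = n_nodes;
  b.learning = learning;
  b.state = 0;
  if (genome.size() >= 2)
    for (size_t pos = 0; pos + 1 < genome.size(); ++pos) {
      if (genome[pos] != CODON_A || genome[pos + 1] != CODON_B) continue;
      Gate gt;
      if (decode_gene(genome, pos, n_nodes, enabled, gt))
        b.gates.push_back(std::move(gt));
      // truncated gene at the genome end: skipped
    }
  return b;
}

// ---------------------------------------------------------------------------
// R <-> C++ brain conversion (R uses 1-based node addresses)
// ---------------------------------------------------------------------------

static std::vector<int> as_int_vec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

static int type_id(const std::string &s) {
  if (s == "deterministic") return GT_DET;
  if (s == "probabilistic") return GT_PROB;
  if (s == "decomposable") return GT_DECOMP;
  if (s == "decomposable_feedback") return GT_DFB;
  if (s == "feedback") return GT_FB;
  stop("unknown gate type: %s", s.c_str());
}

static std::string type_name(int t) {
  switch (t) {
    case GT_DET: return "deterministic";
    case GT_PROB: return "probabilistic";
    case GT_DECOMP: return "decomposable";
    case GT_DFB: return "decomposable_feedback";
    default: return "feedback";
  }
}

static Gate gate_from_R(List gl) {
  Gate g;
  g.type = type_id(as<std::string>(gl["type"]));
  g.ni = as<int>(gl["n_inputs"]);
  g.no = as<int>(gl["n_outputs"]);
  IntegerVector in = gl["inputs"], out = gl["outputs"];
  for (int k = 0; k < g.ni; ++k) g.in[k] = in[k] - 1;
  for (int k = 0; k < g.no; ++k) g.out[k] = out[k] - 1;
  NumericMatrix tb = gl["table"];
  int rows = 1 << g.ni, nO = 1 << g.no;
  g.table.assign((size_t)rows * nO, 0.0);
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < nO; ++c) g.table[(size_t)r * nO + c] = tb(r, c);
  if (gl.containsElementNamed("factors") && !Rf_isNull(gl["factors"])) {
    NumericMatrix fm = gl["factors"];
    g.factors.assign((size_t)rows * g.no, 0.0);
    for (int r = 0; r < rows; ++r)
      for (int j = 0; j < g.no; ++j) g.factors[(size_t)r * g.no + j] = fm(r, j);
  }
  if (gl.containsElementNamed("table0") && !Rf_isNull(gl["table0"])) {
    NumericMatrix tb0 = gl["table0"];
    g.table0.assign((size_t)rows * nO, 0.0);
    for (int r = 0; r < rows; ++r)
      for (int c = 0; c < nO; ++c) g.table0[(size_t)r * nO + c] = tb0(r, c);
  } else {
    g.table0 = g.table;
  }
  if (gl.containsElementNamed("factors0") && !Rf_isNull(gl["factors0"])) {
    NumericMatrix fm0 = gl["factors0"];
    g.factors0.assign((size_t)rows * g.no, 0.0);
    for (int r = 0; r < rows; ++r)
      for (int j = 0; j < g.no; ++j)
        g.factors0[(size_t)r * g.no + j] = fm0(r, j);
  } else {
    g.factors0 = g.factors;
  }
  if (g.feedback_capable()) {
    g.pos_node = as<int>(gl["pos_node"]) - 1;
    g.neg_node = as<int>(gl["neg_node"]) - 1;
    g.hist_len = as<int>(gl["history_length"]);
    NumericVector pd = gl["pos_deltas"], nd = gl["neg_deltas"];
    for (int d = 0; d < 3; ++d) {
      g.pos_delta[d] = pd[d];
      g.neg_delta[d] = nd[d];
    }
    if (gl.containsElementNamed("history") && !Rf_isNull(gl["history"])) {
      IntegerMatrix h = gl["history"];
      g.hist_n = std::min<int>(h.nrow(), 3);
      for (int d = 0; d < g.hist_n; ++d) {
        g.hist_in[d] = h(d, 0);
        g.hist_out[d] = h(d, 1);
      }
    }
  }
  build_wmask(g);
  return g;
}

static List gate_to_R(const Gate &g) {
  int rows = 1 << g.ni, nO = 1 << g.no;
  NumericMatrix tb(rows, nO), tb0(rows, nO);
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < nO; ++c) {
      tb(r, c) = g.table[(size_t)r * nO + c];
      tb0(r, c) = g.table0[(size_t)r * nO + c];
    }
  IntegerVector in(g.ni), out(g.no);
  for (int k = 0; k < g.ni; ++k) in[k] = g.in[k] + 1;
  for (int k = 0; k < g.no; ++k) out[k] = g.out[k] + 1;
  List gl = List::create(
      _["type"] = type_name(g.type), _["n_inputs"] = g.ni,
      _["n_outputs"] = g.no, _["inputs"] = in, _["outputs"] = out,
      _["table"] = tb, _["table0"] = tb0, _["factors"] = R_NilValue,
      _["factors0"] = R_NilValue, _["pos_node"] = R_NilValue,
      _["neg_node"] = R_NilValue, _["history_length"] = R_NilValue,
      _["pos_deltas"] = R_NilValue, _["neg_deltas"] = R_NilValue,
      _["history"] = R_NilValue);
  if (!g.factors.empty()) {
    NumericMatrix fm(rows, g.no), fm0(rows, g.no);
    for (int r = 0; r < rows; ++r)
      for (int j = 0; j < g.no; ++j) {
        fm(r, j) = g.factors[(size_t)r * g.no + j];
        fm0(r, j) = g.factors0[(size_t)r * g.no + j];
      }
    gl["factors"] = fm;
    gl["factors0"] = fm0;
  }
  if (g.feedback_capable()) {
    gl["pos_node"] = g.pos_node + 1;
    gl["neg_node"] = g.neg_node + 1;
    gl["history_length"] = g.hist_len;
    gl["pos_deltas"] = NumericVector(g.pos_delta, g.pos_delta + 3);
    gl["neg_deltas"] = NumericVector(g.neg_delta, g.neg_delta + 3);
    IntegerMatrix h(g.hist_n, 2);
    for (int d = 0; d < g.hist_n; ++d) {
      h(d, 0) = g.hist_in[d];
      h(d, 1) = g.hist_out[d];
    }
    gl["history"] = h;
  }
  gl.attr("class") = "gate";
  return gl;
}

static Brain brain_from_R(List bl) {
  Brain b;
  b.n = as<int>(bl["n_nodes"]);
  b.n_sensors = as<int>(bl["n_sensors"]);
  b.n_motors = as<int>(bl["n_motors"]);
  b.learning = as<bool>(bl["learning_enabled"]);
  std::vector<int> st = as_int_vec(bl["state"]);
  b.state = 0;
  for (int k = 0; k < b.n && k < (int)st.size(); ++k)
    if (st[k]) b.state |= 1u << k;
  List gates = bl["gates"];
  for (R_xlen_t i = 0; i < gates.size(); ++i)
    b.gates.push_back(gate_from_R(gates[i]));
  return b;
}

static List brain_to_R(const Brain &b) {
  List gates(b.gates.size());
  for (size_t i = 0; i < b.gates.size(); ++i) gates[i] = gate_to_R(b.gates[i]);
  List bl = List::create(
      _["n_nodes"] = b.n, _["n_sensors"] = b.n_sensors,
      _["n_motors"] = b.n_motors, _["state"] = [&]() {
        IntegerVector st(b.n);
        for (int k = 0; k < b.n; ++k) st[k] = (b.state >> k) & 1u;
        return st;
      }(),
      _["gates"] = gates, _["learning_enabled"] = b.learning);
  bl.attr("class") = "markov_brain";
  return bl;
}

// [[Rcpp::export]]
List cpp_decode_genome(IntegerVector genome, int n_nodes,
                       IntegerVector enabled_types, bool learning) {
  std::vector<int> g(genome.begin(), genome.end());
  std::vector<int> en(enabled_types.begin(), enabled_types.end());
  Brain b = decode_brain(g, n_nodes, en, learning);
  return brain_to_R(b);
}

// [[Rcpp::export]]
List cpp_brain_step(List brainL, IntegerVector sensor_bits) {
  Brain b = brain_from_R(brainL);
  for (int k = 0; k < b.n_sensors && k < sensor_bits.size(); ++k) {
    if (sensor_bits[k]) b.state |= 1u << k;
    else b.state &= ~(1u << k);
  }
  brain_step(b);
  IntegerVector motors(b.n_motors);
  for (int k = 0; k < b.n_motors; ++k)
    motors[k] = (b.state >> (b.n_sensors + k)) & 1u;
  return List::create(_["brain"] = brain_to_R(b), _["motors"] = motors);
}

// [[Rcpp::export]]
List cpp_apply_feedback(List gateL, bool positive) {
  Gate g = gate_from_R(gateL);
  gate_feedback(g, positive);
  return gate_to_R(g);
}

// ---------------------------------------------------------------------------
// Lattice world + episodes
// ---------------------------------------------------------------------------

struct World {
  int nrow = 0, ncol = 0, goal = 0;
  bool facing = false; // respawn facing the cell's arrow (fixture worlds)
  std::vector<int> wall, arrow, dist, spawn; // cell-indexed; spawn = candidates
};

static World world_from_R(List wl) {
  World w;
  w.nrow = as<int>(wl["nrow"]);
  w.ncol = as<int>(wl["ncol"]);
  w.goal = as<int>(wl["goal0"]);
  w.facing = as<bool>(wl["respawn_facing_arrow"]);
  w.wall = as_int_vec(wl["wall0"]);
  w.arrow = as_int_vec(wl["arrow0"]);
  w.dist = as_int_vec(wl["dist0"]);
  w.spawn = as_int_vec(wl["spawn0"]);
  return w;
}

// orientation/arrow codes: 0=N (row-1), 1=E (col+1), 2=S (row+1), 3=W (col-1)
static inline int neighbor_cell(const World &w, int cell, int dir) {
  int r = cell / w.ncol, c = cell % w.ncol;
  switch (dir) {
    case 0: r--; break;
    case 1: c++; break;
    case 2: r++; break;
    default: c--; break;
  }
  if (r < 0 || r >= w.nrow || c < 0 || c >= w.ncol) return -1;
  return r * w.ncol + c;
}

static inline int draw_int(int n) { // uniform on 0..n-1
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct AgentState {
  int cell = 0, orient = 0;
};

static void respawn(const World &w, AgentState &a) {
  a.cell = w.spawn[draw_int((int)w.spawn.size())];
  int ar = w.arrow[a.cell];
  a.orient = (w.facing && ar >= 0) ? ar : draw_int(4);
}

// Sensor one-hot from the arrow direction relative to the heading:
// node0 = idle signal (arrow undefined), node1 = turn right (90 or 180
// degrees), node2 = forward, node3 = turn left.
static void write_sensors(const World &w, const AgentState &a, Brain &b) {
  b.state &= ~0xFu;
  int ar = w.arrow[a.cell];
  if (ar < 0) {
    b.state |= 1u;
    return;
  }
  int rel = (ar - a.orient + 4) % 4;
  if (rel == 0) b.state |= 4u;      // forward
  else if (rel == 3) b.state |= 8u; // left
  else b.state |= 2u; // 90 right or 180: resolved as a right turn
}

static inline int state_index(const Brain &b) { return (int)b.state; }

struct EpisodeOut {
  int goals = 0;
  int result_counts[4] = {0, 0, 0, 0}; // left, right, idle, forward
  std::vector<int> trace;
  // per-step detail (filled when tracing): action taken, cell and heading
  // before the move resolved, and whether the step reached the goal
  std::vector<int> actions, cells, orients, goal_events;
  std::vector<std::vector<std::vector<double>>> snapshots; // per cp, per gate
};

// results: 0 = left 90, 1 = right 90, 2 = idle, 3 = forward
static void run_episode_core(Brain &b, const World &w, const int *mapping,
                             int lifetime, const std::vector<int> &cps,
                             bool record_trace, bool snapshot, EpisodeOut &eo) {
  AgentState a;
  respawn(w, a);
  if (record_trace) eo.trace.reserve(lifetime + 1);
  size_t cpi = 0;
  auto take_snapshot = [&]() {
    std::vector<std::vector<double>> snap;
    snap.reserve(b.gates.size());
    for (auto &g : b.gates) snap.push_back(g.table);
    eo.snapshots.push_back(std::move(snap));
  };
  if (snapshot && cpi < cps.size() && cps[cpi] == 0) {
    take_snapshot();
    cpi++;
  }
  for (int t = 0; t < lifetime; ++t) {
    write_sensors(w, a, b);
    if (record_trace) eo.trace.push_back(state_index(b));
    brain_step(b);
    int action = 2 * (int)((b.state >> b.n_sensors) & 1u) +
                 (int)((b.state >> (b.n_sensors + 1)) & 1u);
    int result = mapping[action];
    eo.result_counts[result]++;
    if (record_trace) {
      eo.actions.push_back(action);
      eo.cells.push_back(a.cell);
      eo.orients.push_back(a.orient);
    }
    switch (result) {
      case 0: a.orient = (a.orient + 3) % 4; break;
      case 1: a.orient = (a.orient + 1) % 4; break;
      case 3: {
        int tgt = neighbor_cell(w, a.cell, a.orient);
        if (tgt >= 0 && !w.wall[tgt]) a.cell = tgt;
        break;
      }
      default: break; // idle
    }
    bool hit = a.cell == w.goal;
    if (record_trace) eo.goal_events.push_back(hit ? 1 : 0);
    if (hit) {
      eo.goals++;
      respawn(w, a);
    }
    if (snapshot && cpi < cps.size() && cps[cpi] == t + 1) {
      take_snapshot();
      cpi++;
    }
  }
  if (record_trace) eo.trace.push_back(state_index(b));
}

// [[Rcpp::export]]
List cpp_run_episode(List brainL, List worldL, IntegerVector mapping,
                     int lifetime, IntegerVector checkpoints,
                     bool record_trace) {
  Brain b = brain_from_R(brainL);
  World w = world_from_R(worldL);
  int map[4];
  for (int k = 0; k < 4; ++k) map[k] = mapping[k];
  std::vector<int> cps(checkpoints.begin(), checkpoints.end());
  EpisodeOut eo;
  run_episode_core(b, w, map, lifetime, cps, record_trace, !cps.empty(), eo);
  List snaps(eo.snapshots.size());
  for (size_t i = 0; i < eo.snapshots.size(); ++i) {
    List gs(eo.snapshots[i].size());
    for (size_t j = 0; j < eo.snapshots[i].size(); ++j) {
      const Gate &g = b.gates[j];
      int rows = 1 << g.ni, nO = 1 << g.no;
      NumericMatrix tb(rows, nO);
      for (int r = 0; r < rows; ++r)
        for (int c = 0; c < nO; ++c) tb(r, c) = eo.snapshots[i][j][(size_t)r * nO + c];
      gs[j] = tb;
    }
    snaps[i] = gs;
  }
  return List::create(
      _["goals"] = eo.goals,
      _["result_counts"] = IntegerVector(eo.result_counts, eo.result_counts + 4),
      _["trace"] = IntegerVector(eo.trace.begin(), eo.trace.end()),
      _["actions"] = IntegerVector(eo.actions.begin(), eo.actions.end()),
      _["cells"] = IntegerVector(eo.cells.begin(), eo.cells.end()),
      _["orients"] = IntegerVector(eo.orients.begin(), eo.orients.end()),
      _["goal_events"] = IntegerVector(eo.goal_events.begin(),
                                       eo.goal_events.end()),
      _["snapshots"] = snaps, _["brain"] = brain_to_R(b));
}

static int evaluate_brain(Brain &proto, const World &w,
                          const IntegerMatrix &mappings, int lifetime,
                          IntegerVector *per_mapping) {
  int total = 0;
  std::vector<int> no_cps;
  for (int m = 0; m < mappings.nrow(); ++m) {
    Brain b = proto; // fresh tables + states per mapping
    brain_reset_states(b);
    brain_reset_learning(b);
    int map[4];
    for (int k = 0; k < 4; ++k) map[k] = mappings(m, k);
    EpisodeOut eo;
    run_episode_core(b, w, map, lifetime, no_cps, false, false, eo);
    total += eo.goals;
    if (per_mapping) (*per_mapping)[m] = eo.goals;
  }
  return total;
}

// [[Rcpp::export]]
List cpp_evaluate_genome(IntegerVector genome, List worldL,
                         IntegerMatrix mappings, int lifetime, int n_nodes,
                         IntegerVector enabled_types, bool learning) {
  std::vector<int> g(genome.begin(), genome.end());
  std::vector<int> en(enabled_types.begin(), enabled_types.end());
  Brain proto = decode_brain(g, n_nodes, en, learning);
  World w = world_from_R(worldL);
  IntegerVector per(mappings.nrow());
  int total = evaluate_brain(proto, w, mappings, lifetime, &per);
  return List::create(_["g_total"] = total, _["per_mapping"] = per);
}

// ---------------------------------------------------------------------------
// Mutation + GA
// ---------------------------------------------------------------------------

static void find_genes(const std::vector<int> &g,
                       const std::vector<int> &enabled,
                       std::vector<std::pair<size_t, int>> &genes) {
  genes.clear();
  if (g.size() < 2) return;
  for (size_t pos = 0; pos + 1 < g.size(); ++pos) {
    if (g[pos] != CODON_A || g[pos + 1] != CODON_B) continue;
    GeneLayout L;
    if (gene_layout(g, pos, enabled, L)) genes.emplace_back(pos, L.total_len);
  }
}

static std::vector<int> mutate_genome(const std::vector<int> &parent,
                                      const std::vector<int> &enabled,
                                      double point_rate, double dup_rate,
                                      double del_rate, size_t len_min,
                                      size_t len_max) {
  std::vector<int> g = parent;
  // point mutations: binomially many DISTINCT loci redrawn uniformly on
  // 0..255 (exact per-locus Bernoulli semantics via partial Fisher-Yates)
  if (point_rate > 0 && !g.empty()) {
    int L = (int)g.size();
    int nm = (int)R::rbinom((double)L, point_rate);
    if (nm > 0) {
      std::vector<int> idx(L);
      for (int k = 0; k < L; ++k) idx[k] = k;
      for (int m = 0; m < nm; ++m) {
        int j = m + draw_int(L - m);
        std::swap(idx[m], idx[j]);
        g[idx[m]] = draw_int(256);
      }
    }
  }
  std::vector<std::pair<size_t, int>> genes;
  if (dup_rate > 0 && unif_rand() < dup_rate) {
    find_genes(g, enabled, genes);
    if (!genes.empty()) {
      auto pick = genes[draw_int((int)genes.size())];
      if (g.size() + pick.second <= len_max) {
        std::vector<int> block(g.begin() + pick.first,
                               g.begin() + pick.first + pick.second);
        size_t at = (size_t)draw_int((int)g.size() + 1);
        g.insert(g.begin() + at, block.begin(), block.end());
      }
    }
  }
  if (del_rate > 0 && unif_rand() < del_rate) {
    find_genes(g, enabled, genes);
    if (!genes.empty()) {
      auto pick = genes[draw_int((int)genes.size())];
      if (g.size() - pick.second >= len_min)
        g.erase(g.begin() + pick.first, g.begin() + pick.first + pick.second);
    }
  }
  return g;
}

// [[Rcpp::export]]
IntegerVector cpp_mutate(IntegerVector genome, IntegerVector enabled_types,
                         double point_rate, double dup_rate, double del_rate,
                         int len_min, int len_max) {
  std::vector<int> g(genome.begin(), genome.end());
  std::vector<int> en(enabled_types.begin(), enabled_types.end());
  std::vector<int> out = mutate_genome(g, en, point_rate, dup_rate, del_rate,
                                       (size_t)len_min, (size_t)len_max);
  return IntegerVector(out.begin(), out.end());
}

static double fnv1a32(const std::vector<int> &g) {
  uint32_t h = 2166136261u;
  for (int v : g) {
    h ^= (uint32_t)(v & 0xff);
    h *= 16777619u;
  }
  return (double)h;
}

// [[Rcpp::export]]
double cpp_genome_hash(IntegerVector genome) {
  std::vector<int> g(genome.begin(), genome.end());
  return fnv1a32(g);
}

static int tournament(const std::vector<double> &fit, int tsize) {
  int n = (int)fit.size();
  std::vector<int> drawn(tsize);
  for (int k = 0; k < tsize; ++k) drawn[k] = draw_int(n);
  double best = -1.0;
  for (int k = 0; k < tsize; ++k) best = std::max(best, fit[drawn[k]]);
  std::vector<int> ties;
  for (int k = 0; k < tsize; ++k)
    if (fit[drawn[k]] == best) ties.push_back(drawn[k]);
  return ties[draw_int((int)ties.size())];
}

// [[Rcpp::export]]
int cpp_tournament_select(NumericVector fitness, int tournament_size) {
  std::vector<double> f(fitness.begin(), fitness.end());
  return tournament(f, tournament_size) + 1; // 1-based index for R
}

// Generational GA. Archives (generation, id, parent, fitness, hash) for every
// individual and keeps genomes for all ancestors of the current population
// (pruned periodically), so the line of descent can be reconstructed with its
// genomes after the run.
// [[Rcpp::export]]
List cpp_evolve(List init_genomes, List worldL, IntegerMatrix fit_mappings,
                int lifetime, int generations, int n_nodes,
                IntegerVector enabled_types, bool learning,
                int tournament_size, double point_rate, double dup_rate,
                double del_rate, int len_min, int len_max) {
  World w = world_from_R(worldL);
  std::vector<int> en(enabled_types.begin(), enabled_types.end());
  int P = (int)init_genomes.size();
  std::vector<std::vector<int>> pop(P);
  for (int i = 0; i < P; ++i) pop[i] = as_int_vec(init_genomes[i]);

  long next_id = 0;
  std::vector<long> ids(P), parents(P, -1);
  for (int i = 0; i < P; ++i) ids[i] = next_id++;
  std::unordered_map<long, long> parent_of;
  std::unordered_map<long, std::vector<int>> store;
  for (int i = 0; i < P; ++i) {
    parent_of[ids[i]] = -1;
    store[ids[i]] = pop[i];
  }

  int G = generations;
  size_t nrec = (size_t)(G + 1) * P;
  IntegerVector a_gen(nrec), a_id(nrec), a_parent(nrec);
  NumericVector a_fit(nrec), a_hash(nrec);
  size_t rec = 0;

  std::vector<double> fit(P);
  for (int gen = 0; gen <= G; ++gen) {
    for (int i = 0; i < P; ++i) {
      Brain proto = decode_brain(pop[i], n_nodes, en, learning);
      fit[i] = (double)evaluate_brain(proto, w, fit_mappings, lifetime,
                                      nullptr);
      a_gen[rec] = gen;
      a_id[rec] = (int)ids[i];
      a_parent[rec] = (int)parents[i];
      a_fit[rec] = fit[i];
      a_hash[rec] = fnv1a32(pop[i]);
      rec++;
    }
    if (gen == G) break;
    std::vector<std::vector<int>> newpop(P);
    std::vector<long> newids(P), newparents(P);
    for (int k = 0; k < P; ++k) {
      int pi = tournament(fit, tournament_size);
      newpop[k] = mutate_genome(pop[pi], en, point_rate, dup_rate, del_rate,
                                (size_t)len_min, (size_t)len_max);
      newids[k] = next_id++;
      newparents[k] = ids[pi];
      parent_of[newids[k]] = ids[pi];
      store[newids[k]] = newpop[k];
    }
    pop.swap(newpop);
    ids.swap(newids);
    parents.swap(newparents);
    // prune genome store to ancestors of the living population
    if (gen % 50 == 49) {
      std::unordered_set<long> keep;
      for (int i = 0; i < P; ++i) {
        long cur = ids[i];
        while (cur >= 0 && keep.insert(cur).second) {
          auto it = parent_of.find(cur);
          cur = (it == parent_of.end()) ? -1 : it->second;
        }
      }
      for (auto it = store.begin(); it != store.end();)
        it = keep.count(it->first) ? std::next(it) : store.erase(it);
    }
    if (gen % 100 == 0) Rcpp::checkUserInterrupt();
  }

  // final prune + export store
  std::unordered_set<long> keep;
  for (int i = 0; i < P; ++i) {
    long cur = ids[i];
    while (cur >= 0 && keep.insert(cur).second) {
      auto it = parent_of.find(cur);
      cur = (it == parent_of.end()) ? -1 : it->second;
    }
  }
  std::vector<long> kept(keep.begin(), keep.end());
  std::sort(kept.begin(), kept.end());
  List store_genomes(kept.size());
  IntegerVector store_ids(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    store_ids[i] = (int)kept[i];
    auto it = store.find(kept[i]);
    if (it != store.end())
      store_genomes[i] = IntegerVector(it->second.begin(), it->second.end());
    else
      store_genomes[i] = R_NilValue;
  }
  IntegerVector final_ids(P);
  for (int i = 0; i < P; ++i) final_ids[i] = (int)ids[i];

  return List::create(
      _["generation"] = a_gen, _["id"] = a_id, _["parent_id"] = a_parent,
      _["fitness"] = a_fit, _["genome_hash"] = a_hash,
      _["final_ids"] = final_ids, _["store_ids"] = store_ids,
      _["store_genomes"] = store_genomes);
}

// ---------------------------------------------------------------------------
// Transition probability matrices
// ---------------------------------------------------------------------------

// Exact next-state distribution for every start state, by enumerating the
// joint outcome space of all gates (gates fire independently; writes OR).
// [[Rcpp::export]]
NumericMatrix cpp_analytic_tpm(List brainL) {
  Brain b = brain_from_R(brainL);
  if (b.n > 14) stop("analytic TPM limited to 14 nodes");
  int S = 1 << b.n;
  NumericMatrix tpm(S, S);
  std::vector<double> dist(S), nxt(S);
  for (int s = 0; s < S; ++s) {
    std::fill(dist.begin(), dist.end(), 0.0);
    dist[0] = 1.0; // default-0 baseline before any gate writes
    for (auto &g : b.gates) {
      int pat = 0;
      for (int k = 0; k < g.ni; ++k)
        pat = (pat << 1) | ((s >> g.in[k]) & 1);
      int nO = 1 << g.no;
      const double *row = &g.table[(size_t)pat * nO];
      std::fill(nxt.begin(), nxt.end(), 0.0);
      for (int t = 0; t < S; ++t) {
        if (dist[t] == 0.0) continue;
        for (int p = 0; p < nO; ++p) {
          if (row[p] == 0.0) continue;
          nxt[t | (int)g.wmask[p]] += dist[t] * row[p];
        }
      }
      dist.swap(nxt);
    }
    for (int t = 0; t < S; ++t) tpm(s, t) = dist[t];
  }
  return tpm;
}

// Monte-Carlo transition counts: for every start state, run the one-step
// update k times (learning disabled during measurement) and count arrival
// states. Returned as sparse (from, to, count) triplets, 0-based states.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_transitions(List brainL, int samples_per_state) {
  Brain b = brain_from_R(brainL);
  b.learning = false;
  if (b.n > 26) stop("too many nodes to enumerate start states");
  long S = 1L << b.n;
  std::unordered_map<uint64_t, int> counts;
  Brain work = b;
  for (long s = 0; s < S; ++s) {
    for (int rep = 0; rep < samples_per_state; ++rep) {
      work.state = (uint32_t)s;
      brain_step(work);
      uint64_t key = ((uint64_t)s << 26) | (uint64_t)state_index(work);
      counts[key]++;
    }
    if ((s & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out((int)counts.size(), 3);
  int i = 0;
  for (auto &kv : counts) {
    out(i, 0) = (int)(kv.first >> 26);
    out(i, 1) = (int)(kv.first & ((1u << 26) - 1));
    out(i, 2) = kv.second;
    i++;
  }
  return out;
}
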