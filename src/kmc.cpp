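// Direct-method stochastic simulation of chain-growth copolymerization with
// explicit per-chain bookkeeping.  Channel-grouped propensities: chains are
// held in per-(status, terminal) index groups so every SSA step costs
// O(#channels) regardless of population size.
//
// Status codes: 0 active, 1 dormant (ATRP), 2 macromonomer, 3 dead,
//               -1 removed (absorbed by macropropagation / merged away).
//
// Channel kind codes (mirrored in R/network.R):
//   1  initiation            I + M_j           -> new active chain (CL = 1)
//   2  propagation           P(i) + M_j        -> CL+1, terminal j
//   3  transfer_to_monomer   P(i) + M_j        -> macromonomer + new P(1,j)
//   4  macropropagation      P(i) + D          -> merged chain, branch+1
//   5  quench                P(any) + Term     -> dead chain
//   6  atrp_activation_i     R0X + Act         -> R0. + Deact
//   7  atrp_deactivation_i   R0. + Deact       -> R0X + Act
//   8  atrp_initiation       R0. + M_j         -> new active chain (CL = 1)
//   9  atrp_activation       Dorm(i) + Act     -> P(i) + Deact
//  10  atrp_deactivation     P(i) + Deact      -> Dorm(i) + Act
//  11  atrp_termination      P + P             -> dead chain(s)

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in (0, 1); 53-bit mantissa, never exactly 0 or 1
  double unif() {
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

struct Event {
  int type;          // 1 feed M1, 2 feed M2, 3 feed initiator, 4 feed activator, 5 quench
  int trigger_kind;  // 1 overall conversion, 2 M1 conversion, 3 M2 conversion, 4 time
  double trigger;
  double amount;
  bool done;
};

class Engine {
 public:
  // population
  std::vector<int> n1, n2, term, status, branch, pos;
  std::vector<std::string> seq;
  bool record_seq = false;

  // index groups (terminal index 0-based)
  std::vector<int> act[2], dorm[2], macro;

  // small molecules (molecule counts)
  double nI = 0, nM[2] = {0, 0}, nR0 = 0, nAct = 0, nDeact = 0, nTerm = 0;
  double addedM[2] = {0, 0};     // total monomer ever charged, per type
  double uInc[2] = {0, 0};       // monomer units incorporated in chains
  double aborted[2] = {0, 0};    // consumed by suppressed re-initiation (ablation)

  // running aggregates over live records (status >= 0)
  double nChains = 0, nDead = 0, nBranched = 0;
  double unitsTotal = 0, sumCL2 = 0;

  // channels
  std::vector<int> ckind, ci, cj;
  std::vector<double> crate;
  double bimol = 0;  // 1 / (N_A * V)

  bool disableReinit = false;
  int termMode = 1;  // 1 combination, 2 disproportionation

  // event tallies by kind (1..11)
  std::vector<double> tally = std::vector<double>(12, 0.0);

  double t = 0;
  Rng rng;

  explicit Engine(uint64_t seed) : rng(seed) {}

  int nLive() const { return static_cast<int>(nChains); }

  void grpAdd(std::vector<int>& g, int id) {
    pos[id] = static_cast<int>(g.size());
    g.push_back(id);
  }
  void grpRemove(std::vector<int>& g, int id) {
    int p = pos[id];
    int last = g.back();
    g[p] = last;
    pos[last] = p;
    g.pop_back();
  }
  std::vector<int>& groupOf(int id) {
    if (status[id] == 0) return act[term[id]];
    if (status[id] == 1) return dorm[term[id]];
    return macro;  // status 2
  }

  int newChain(int mono, int stat) {  // mono 0-based
    n1.push_back(mono == 0 ? 1 : 0);
    n2.push_back(mono == 1 ? 1 : 0);
    term.push_back(mono);
    status.push_back(stat);
    branch.push_back(0);
    pos.push_back(-1);
    if (record_seq) seq.push_back(mono == 0 ? "1" : "2");
    int id = static_cast<int>(n1.size()) - 1;
    if (stat == 0) grpAdd(act[mono], id);
    nChains += 1;
    unitsTotal += 1;
    sumCL2 += 1;
    uInc[mono] += 1;
    return id;
  }

  int cl(int id) const { return n1[id] + n2[id]; }

  double consumed(int m) const { return addedM[m] - nM[m]; }
  double convMono(int m) const {
    return addedM[m] > 0 ? consumed(m) / addedM[m] : 0.0;
  }
  double convOverall() const {
    double tot = addedM[0] + addedM[1];
    return tot > 0 ? (consumed(0) + consumed(1)) / tot : 0.0;
  }

  double propensity(int c) const {
    double k = crate[c];
    switch (ckind[c]) {
      case 1:  return k * bimol * nI * nM[cj[c]];
      case 2:  return k * bimol * act[ci[c]].size() * nM[cj[c]];
      case 3:  return k * bimol * act[ci[c]].size() * nM[cj[c]];
      case 4:  return k * bimol * act[ci[c]].size() * macro.size();
      case 5:  return k * bimol * (act[0].size() + act[1].size()) * nTerm;
      case 6:  return k * bimol * nI * nAct;
      case 7:  return k * bimol * nR0 * nDeact;
      case 8:  return k * bimol * nR0 * nM[cj[c]];
      case 9:  return k * bimol * dorm[ci[c]].size() * nAct;
      case 10: return k * bimol * act[ci[c]].size() * nDeact;
      case 11: {
        double n = act[0].size() + act[1].size();
        return k * bimol * n * (n - 1);
      }
      default: return 0.0;
    }
  }

  int pickActive(int i) { return act[i][rng.below(act[i].size())]; }

  void propagate(int id, int j) {
    double L = cl(id);
    sumCL2 += 2 * L + 1;
    unitsTotal += 1;
    if (j == 0) n1[id] += 1; else n2[id] += 1;
    uInc[j] += 1;
    nM[j] -= 1;
    if (term[id] != j && status[id] == 0) {
      grpRemove(act[term[id]], id);
      term[id] = j;
      grpAdd(act[j], id);
    } else {
      term[id] = j;
    }
    if (record_seq) seq[id] += (j == 0 ? '1' : '2');
  }

  void makeDead(int id) {
    if (status[id] == 0) grpRemove(act[term[id]], id);
    else if (status[id] == 1) grpRemove(dorm[term[id]], id);
    else if (status[id] == 2) grpRemove(macro, id);
    status[id] = 3;
    nDead += 1;
  }

  void fire(int c) {
    int kind = ckind[c];
    tally[kind] += 1;
    switch (kind) {
      case 1: {  // initiation
        int j = cj[c];
        nI -= 1;
        nM[j] -= 1;
        newChain(j, 0);
        break;
      }
      case 2: {  // propagation
        propagate(pickActive(ci[c]), cj[c]);
        break;
      }
      case 3: {  // transfer to monomer: chain -> macromonomer, monomer -> new carrier
        int id = pickActive(ci[c]);
        int j = cj[c];
        grpRemove(act[term[id]], id);
        status[id] = 2;
        grpAdd(macro, id);
        nM[j] -= 1;
        if (disableReinit) {
          aborted[j] += 1;
        } else {
          newChain(j, 0);
        }
        break;
      }
      case 4: {  // macropropagation: active chain absorbs a macromonomer
        int id = pickActive(ci[c]);
        int d = macro[rng.below(macro.size())];
        double a = cl(id), b = cl(d);
        sumCL2 += 2 * a * b;  // (a+b)^2 - a^2 - b^2
        bool wasBranched = branch[id] >= 1;
        n1[id] += n1[d];
        n2[id] += n2[d];
        branch[id] += branch[d] + 1;
        if (!wasBranched) nBranched += 1;
        if (branch[d] >= 1) nBranched -= 1;
        if (record_seq) seq[id] += "(" + seq[d] + ")";
        grpRemove(macro, d);
        status[d] = -1;
        nChains -= 1;
        break;
      }
      case 5: {  // kinetic quench by terminator
        int nA = static_cast<int>(act[0].size() + act[1].size());
        int r = rng.below(nA);
        int id = r < static_cast<int>(act[0].size())
                     ? act[0][r]
                     : act[1][r - act[0].size()];
        makeDead(id);
        nTerm -= 1;
        break;
      }
      case 6: nI -= 1; nAct -= 1; nR0 += 1; nDeact += 1; break;
      case 7: nR0 -= 1; nDeact -= 1; nI += 1; nAct += 1; break;
      case 8: {  // ATRP chain initiation from activated initiator radical
        int j = cj[c];
        nR0 -= 1;
        nM[j] -= 1;
        newChain(j, 0);
        break;
      }
      case 9: {  // dormant -> active
        int i = ci[c];
        int id = dorm[i][rng.below(dorm[i].size())];
        grpRemove(dorm[i], id);
        status[id] = 0;
        grpAdd(act[i], id);
        nAct -= 1;
        nDeact += 1;
        break;
      }
      case 10: {  // active -> dormant
        int id = pickActive(ci[c]);
        grpRemove(act[ci[c]], id);
        status[id] = 1;
        grpAdd(dorm[ci[c]], id);
        nDeact -= 1;
        nAct += 1;
        break;
      }
      case 11: {  // radical-radical termination
        int nA = static_cast<int>(act[0].size() + act[1].size());
        int r1i = rng.below(nA), r2i = rng.below(nA - 1);
        if (r2i >= r1i) r2i += 1;
        auto chainAt = [&](int r) {
          return r < static_cast<int>(act[0].size())
                     ? act[0][r]
                     : act[1][r - act[0].size()];
        };
        int a = chainAt(r1i), b = chainAt(r2i);
        if (termMode == 1) {  // combination: merge into one dead chain
          double La = cl(a), Lb = cl(b);
          sumCL2 += 2 * La * Lb;
          bool aB = branch[a] >= 1, bB = branch[b] >= 1;
          n1[a] += n1[b];
          n2[a] += n2[b];
          branch[a] += branch[b];
          if (aB && bB) nBranched -= 1;
          if (record_seq) seq[a] += "+" + seq[b];
          grpRemove(act[term[b]], b);
          status[b] = -1;
          nChains -= 1;
          makeDead(a);
        } else {  // disproportionation: two dead chains, counts preserved
          makeDead(a);
          makeDead(b);
        }
        break;
      }
      default:
        stop("internal error: unknown channel kind");
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".kmc_run")]]
List kmc_run(List channels, List init, List ctrl) {
  IntegerVector kind = channels["kind"];
  IntegerVector ti = channels["terminal"];
  IntegerVector mj = channels["monomer"];
  NumericVector rate = channels["rate"];

  Engine e(static_cast<uint64_t>(as<double>(ctrl["seed"])));
  int nc = kind.size();
  for (int c = 0; c < nc; ++c) {
    e.ckind.push_back(kind[c]);
    e.ci.push_back(ti[c] > 0 ? ti[c] - 1 : 0);
    e.cj.push_back(mj[c] > 0 ? mj[c] - 1 : 0);
    e.crate.push_back(rate[c]);
  }

  e.bimol = as<double>(ctrl["bimol_scale"]);
  e.disableReinit = as<bool>(ctrl["disable_reinitiation"]);
  e.termMode = as<int>(ctrl["termination_mode"]);
  e.record_seq = as<bool>(ctrl["record_sequences"]);

  e.nI = as<double>(init["n_initiator"]);
  NumericVector m0 = init["n_monomer"];
  e.nM[0] = m0[0];
  e.nM[1] = m0[1];
  e.addedM[0] = m0[0];
  e.addedM[1] = m0[1];
  e.nAct = as<double>(init["n_activator"]);
  e.nDeact = as<double>(init["n_deactivator"]);
  e.nTerm = as<double>(init["n_terminator"]);

  bool instantInit = as<bool>(ctrl["instant_init"]);
  double stopConv = as<double>(ctrl["stop_conversion"]);
  double maxTime = as<double>(ctrl["max_time"]);
  double maxEvents = as<double>(ctrl["max_events"]);
  bool quenchAtEnd = as<bool>(ctrl["quench_at_end"]);

  NumericVector grid = ctrl["snapshot_grid"];
  NumericVector popAt = ctrl["record_populations_at"];

  // scheduled feed/quench events
  std::vector<Event> events;
  List evl = ctrl["events"];
  for (int i = 0; i < evl.size(); ++i) {
    List ev = evl[i];
    events.push_back({as<int>(ev["type"]), as<int>(ev["trigger_kind"]),
                      as<double>(ev["trigger"]), as<double>(ev["amount"]), false});
  }

  if (instantInit) {
    // all initiator converted to unit-length chains at t = 0
    while (e.nI > 0 && (e.nM[0] + e.nM[1]) > 0) {
      double u = e.rng.unif() * (e.nM[0] + e.nM[1]);
      int j = (u < e.nM[0]) ? 0 : 1;
      e.nI -= 1;
      e.nM[j] -= 1;
      e.newChain(j, 0);
    }
  }

  // snapshot storage
  std::vector<std::vector<double>> snap;
  auto takeSnapshot = [&]() {
    double nLive = e.nChains;
    double xn = nLive > 0 ? e.unitsTotal / nLive : 0.0;
    double xw = e.unitsTotal > 0 ? e.sumCL2 / e.unitsTotal : 0.0;
    double nmac = e.macro.size();
    snap.push_back({e.t, e.convOverall(), e.convMono(0), e.convMono(1),
                    e.nI, e.nM[0], e.nM[1], nLive,
                    static_cast<double>(e.act[0].size() + e.act[1].size()),
                    static_cast<double>(e.dorm[0].size() + e.dorm[1].size()),
                    nmac, e.nDead, e.uInc[0], e.uInc[1], xn, xw,
                    xn > 0 ? xw / xn : 0.0,
                    nLive > 0 ? nmac / nLive : 0.0,
                    nLive > 0 ? e.nBranched / nLive : 0.0,
                    e.nAct, e.nDeact, e.nR0,
                    e.tally[1] + e.tally[2] + e.tally[3] + e.tally[4] +
                        e.tally[5] + e.tally[6] + e.tally[7] + e.tally[8] +
                        e.tally[9] + e.tally[10] + e.tally[11]});
  };

  auto collectPop = [&](List& out) {
    int n = e.n1.size();
    std::vector<int> keep;
    keep.reserve(n);
    for (int i = 0; i < n; ++i)
      if (e.status[i] >= 0) keep.push_back(i);
    int m = keep.size();
    IntegerVector o1(m), o2(m), ot(m), os(m), ob(m);
    for (int i = 0; i < m; ++i) {
      int id = keep[i];
      o1[i] = e.n1[id];
      o2[i] = e.n2[id];
      ot[i] = e.term[id] + 1;
      os[i] = e.status[id];
      ob[i] = e.branch[id];
    }
    out["n1"] = o1;
    out["n2"] = o2;
    out["terminal"] = ot;
    out["status"] = os;
    out["branch"] = ob;
    if (e.record_seq) {
      CharacterVector sq(m);
      for (int i = 0; i < m; ++i) sq[i] = e.seq[keep[i]];
      out["sequence"] = sq;
    }
  };

  takeSnapshot();
  std::size_t gridNext = 0;
  while (gridNext < static_cast<std::size_t>(grid.size()) &&
         grid[gridNext] <= e.convOverall())
    ++gridNext;
  std::size_t popNext = 0;
  List popRecords;
  std::vector<double> popConv;

  double nEvents = 0;
  bool stalled = false;
  bool hardQuench = false;

  auto applyScheduled = [&](Event& ev) {
    ev.done = true;
    switch (ev.type) {
      case 1: e.nM[0] += ev.amount; e.addedM[0] += ev.amount; break;
      case 2: e.nM[1] += ev.amount; e.addedM[1] += ev.amount; break;
      case 3: e.nI += ev.amount; break;
      case 4: e.nAct += ev.amount; break;
      case 5: {  // instantaneous quench: all active (and dormant) chains die
        for (int i = 0; i < 2; ++i) {
          while (!e.act[i].empty()) e.makeDead(e.act[i].back());
          while (!e.dorm[i].empty()) e.makeDead(e.dorm[i].back());
        }
        hardQuench = true;  // the batch is terminated: end the run normally
        break;
      }
    }
  };

  auto convTriggerValue = [&](int kindT) {
    if (kindT == 1) return e.convOverall();
    if (kindT == 2) return e.convMono(0);
    return e.convMono(1);
  };

  bool quenched = false;
  while (true) {
    // conversion-triggered scheduled events
    for (auto& ev : events)
      if (!ev.done && ev.trigger_kind != 4 &&
          convTriggerValue(ev.trigger_kind) >= ev.trigger)
        applyScheduled(ev);
    if (hardQuench || e.convOverall() >= stopConv) break;

    double atot = 0;
    std::vector<double> a(nc);
    for (int c = 0; c < nc; ++c) {
      a[c] = e.propensity(c);
      atot += a[c];
    }

    // next pending time-triggered event
    double tNextEvent = R_PosInf;
    int evIdx = -1;
    for (std::size_t i = 0; i < events.size(); ++i)
      if (!events[i].done && events[i].trigger_kind == 4 &&
          events[i].trigger < tNextEvent) {
        tNextEvent = events[i].trigger;
        evIdx = static_cast<int>(i);
      }

    if (atot <= 0) {
      if (evIdx >= 0) {
        e.t = tNextEvent;
        applyScheduled(events[evIdx]);
        continue;
      }
      if (e.convOverall() < stopConv) stalled = true;
      break;
    }

    double tau = -std::log(e.rng.unif()) / atot;
    if (e.t + tau >= tNextEvent) {
      e.t = tNextEvent;
      applyScheduled(events[evIdx]);
      continue;
    }
    if (e.t + tau > maxTime) {
      e.t = maxTime;
      break;
    }
    e.t += tau;

    double u = e.rng.unif() * atot;
    int c = 0;
    double acc = a[0];
    while (acc < u && c < nc - 1) acc += a[++c];
    e.fire(c);
    nEvents += 1;

    double xo = e.convOverall();
    while (gridNext < static_cast<std::size_t>(grid.size()) &&
           xo >= grid[gridNext]) {
      takeSnapshot();
      ++gridNext;
    }
    while (popNext < static_cast<std::size_t>(popAt.size()) &&
           xo >= popAt[popNext]) {
      List p;
      collectPop(p);
      popRecords.push_back(p);
      popConv.push_back(popAt[popNext]);
      ++popNext;
    }
    if (nEvents >= maxEvents) break;
  }

  if (quenchAtEnd && !stalled) {
    for (int i = 0; i < 2; ++i) {
      while (!e.act[i].empty()) e.makeDead(e.act[i].back());
      while (!e.dorm[i].empty()) e.makeDead(e.dorm[i].back());
    }
    quenched = true;
  }
  takeSnapshot();

  int ns = snap.size();
  NumericMatrix smat(ns, 23);
  for (int r = 0; r < ns; ++r)
    for (int k = 0; k < 23; ++k) smat(r, k) = snap[r][k];

  List finalPop;
  collectPop(finalPop);

  NumericVector tallies(11);
  for (int k = 1; k <= 11; ++k) tallies[k - 1] = e.tally[k];

  return List::create(
      _["snapshots"] = smat, _["population"] = finalPop,
      _["populations"] = popRecords, _["population_conversions"] = wrap(popConv),
      _["tallies"] = tallies, _["time"] = e.t, _["n_events"] = nEvents,
      _["stalled"] = stalled, _["quenched"] = quenched,
      _["aborted_reinitiations"] = NumericVector::create(e.aborted[0], e.aborted[1]),
      _["added_monomer"] = NumericVector::create(e.addedM[0], e.addedM[1]),
      _["free_monomer"] = NumericVector::create(e.nM[0], e.nM[1]),
      _["incorporated"] = NumericVector::create(e.uInc[0], e.uInc[1]),
      _["conversion"] = NumericVector::create(e.convOverall(), e.convMono(0),
                                              e.convMono(1)));
}
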