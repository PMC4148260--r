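#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Toroidal wrap of a coordinate onto [0, m).
static inline int wrap_i(int x, int m) {
  int y = x % m;
  if (y < 0) y += m;
  return y;
}

// Uniform integer on {0, ..., n-1} from R's RNG stream; consumes exactly
// one uniform so the pure-R engine can mirror the stream draw for draw.
static inline int draw_int(int n) {
  int j = (int)(unif_rand() * n);
  if (j >= n) j = n - 1;
  return j;
}

// Random-sequential update engine. Sites are 0-based column-major linear
// indices (idx = row + col * n_rows), matching R matrix storage. All
// stochastic choices consume R's global RNG in a fixed order per round:
// focal site, partner offset, [role model | adoption] for focal then
// partner, noise for focal then partner. Punishment consumes no draws.
//
// punish_mode: 0 none, 1 behavior-based, 2 preference-based,
//              3 adaptive group pressure (behavior-based trigger).
// [[Rcpp::export]]
List engine_run(IntegerVector preference, IntegerVector behavior,
                NumericVector last_payoff, NumericVector cumulative_payoff,
                int n_rows, int n_cols, int t_start, int n_steps,
                double A, double B, double r,
                IntegerMatrix offsets,
                int punish_mode, double C, double k_fine, double C0,
                bool mutual, bool record_events, double stop_share) {
  const int n = n_rows * n_cols;
  const int n_off = offsets.nrow();
  const int rounds = n / 2;

  IntegerVector beh = clone(behavior);
  NumericVector lp = clone(last_payoff);
  NumericVector cum = clone(cumulative_payoff);

  // neighbor table: neighbors are immutable, so resolve the toroidal
  // wrap once; nbrtab[i * n_off + o] is site i's o-th neighbor, in the
  // deterministic row-major offset order
  std::vector<int> nbrtab((size_t)n * n_off);
  for (int i = 0; i < n; ++i) {
    int row = i % n_rows, col = i / n_rows;
    for (int o = 0; o < n_off; ++o) {
      int nr = wrap_i(row + offsets(o, 0), n_rows);
      int nc = wrap_i(col + offsets(o, 1), n_cols);
      nbrtab[(size_t)i * n_off + o] = nr + nc * n_rows;
    }
  }

  // preferences never change: precompute each agent's eligible role
  // models (same-preference neighbors), preserving offset order
  std::vector<int> elig;
  elig.reserve((size_t)n * n_off / 2);
  std::vector<int> elig_start(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < n_off; ++o) {
      int s = nbrtab[(size_t)i * n_off + o];
      if (preference[s] == preference[i]) elig.push_back(s);
    }
    elig_start[i + 1] = (int)elig.size();
  }

  std::vector<int> m_t;
  std::vector<double> m_s1, m_spref, m_mp;
  std::vector<int> m_sin, m_hyp;
  std::vector<int> ev_t, ev_per, ev_pee, ev_hyp;
  std::vector<double> ev_cost, ev_fine;

  double total_gross = 0.0;
  int t = t_start;
  bool stopped = false;
  int sin_count = 0, hyp_count = 0;

  // fraction of ego's neighbors whose behavior differs from ego's
  auto nonconf = [&](int ego) -> double {
    const int *nb = &nbrtab[(size_t)ego * n_off];
    int d = 0;
    for (int o = 0; o < n_off; ++o)
      if (beh[nb[o]] != beh[ego]) ++d;
    return (double)d / (double)n_off;
  };

  // ego may sanction alter; modifies net round payoffs and cumulative
  // payoffs in place; the solvency guard is checked against cumulative
  // payoff before this round's interaction payoff is credited
  auto punish = [&](int ego, int alter, double &net_ego, double &net_alter) {
    bool trigger = (punish_mode == 2) ? (beh[alter] != preference[ego])
                                      : (beh[alter] != beh[ego]);
    if (!trigger) return;
    double cost;
    if (punish_mode == 3) {
      double u = 1.0 - nonconf(ego);
      double v = 2.0 - u * u;
      cost = C0 * u * u * u * u * v * v;
    } else {
      cost = C;
    }
    if (cum[ego] - cost < 0) return;
    double fine = k_fine * cost;
    cum[ego] -= cost;
    cum[alter] -= fine;
    net_ego -= cost;
    net_alter -= fine;
    bool hyp = (punish_mode == 2) ? (beh[alter] == beh[ego])
                                  : (beh[alter] == preference[ego]);
    if (hyp) ++hyp_count; else ++sin_count;
    if (record_events) {
      ev_t.push_back(t + 1);
      ev_per.push_back(ego + 1);
      ev_pee.push_back(alter + 1);
      ev_hyp.push_back(hyp ? 1 : 0);
      ev_cost.push_back(cost);
      ev_fine.push_back(fine);
    }
  };

  // proportional imitation of a uniform same-preference neighbor; the
  // role-model draw is consumed iff the eligible set is non-empty, the
  // adoption draw iff the model's last payoff is strictly higher
  auto imitate = [&](int agent) {
    int m = elig_start[agent + 1] - elig_start[agent];
    if (m == 0) return;
    int model = elig[elig_start[agent] + draw_int(m)];
    double d = lp[model] - lp[agent];
    if (d <= 0) return;
    double prob = d / (A + B);
    if (prob > 1.0) prob = 1.0;
    if (unif_rand() < prob) beh[agent] = beh[model];
  };

  auto noise = [&](int agent) {
    if (unif_rand() < r) beh[agent] = 3 - beh[agent];
  };

  for (int step = 0; step < n_steps; ++step) {
    sin_count = 0;
    hyp_count = 0;
    for (int round = 0; round < rounds; ++round) {
      int focal = draw_int(n);
      int partner = nbrtab[(size_t)focal * n_off + draw_int(n_off)];
      double Pb = A * (beh[focal] == beh[partner]) +
                  B * (beh[focal] == preference[focal]);
      double Pc = A * (beh[partner] == beh[focal]) +
                  B * (beh[partner] == preference[partner]);
      total_gross += Pb + Pc;
      double net_f = Pb, net_p = Pc;
      if (punish_mode > 0) {
        punish(focal, partner, net_f, net_p);
        if (mutual) punish(partner, focal, net_p, net_f);
      }
      lp[focal] = net_f;
      lp[partner] = net_p;
      cum[focal] += Pb;
      cum[partner] += Pc;
      imitate(focal);
      imitate(partner);
      noise(focal);
      noise(partner);
    }
    ++t;
    int c1 = 0, cp = 0;
    double mp = 0.0;
    for (int i = 0; i < n; ++i) {
      if (beh[i] == 1) ++c1;
      if (beh[i] == preference[i]) ++cp;
      mp += lp[i];
    }
    double s1 = (double)c1 / n;
    m_t.push_back(t);
    m_s1.push_back(s1);
    m_spref.push_back((double)cp / n);
    m_mp.push_back(mp / n);
    m_sin.push_back(sin_count);
    m_hyp.push_back(hyp_count);
    if (stop_share > 0 && (s1 >= stop_share || 1.0 - s1 >= stop_share)) {
      stopped = true;
      break;
    }
  }

  return List::create(
      _["behavior"] = beh, _["last_payoff"] = lp,
      _["cumulative_payoff"] = cum, _["t"] = t,
      _["metrics"] = List::create(
          _["t"] = wrap(m_t), _["share_b1"] = wrap(m_s1),
          _["share_preferred"] = wrap(m_spref), _["mean_payoff"] = wrap(m_mp),
          _["n_sanctions_sincere"] = wrap(m_sin),
          _["n_sanctions_hypocritical"] = wrap(m_hyp)),
      _["events"] = List::create(
          _["t"] = wrap(ev_t), _["punisher"] = wrap(ev_per),
          _["punishee"] = wrap(ev_pee), _["hypocritical"] = wrap(ev_hyp),
          _["cost"] = wrap(ev_cost), _["fine"] = wrap(ev_fine)),
      _["total_gross_payoff"] = total_gross, _["stopped"] = stopped);
}
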