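// Core 1-ms-grid simulation loop: Izhikevich population stepping with
// current-based synapses plus the per-step injection protocol (target-set
// perturbation, band/ramp count draws, uniform subset selection).
//
// All protocol randomness is drawn from a single std::mt19937 stream seeded
// from R (the "selection" sub-seed), so a run is reproducible given
// (realized circuit, designated pools, seed).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;


// Unbiased uniform integer in [0, n), n >= 1.
static inline int runif_int(std::mt19937 &rng, int n) {
  uint32_t un = (uint32_t)n;
  uint32_t lim = UINT32_MAX - (UINT32_MAX % un);
  uint32_t x;
  do {
    x = rng();
  } while (x >= lim);
  return (int)(x % un);
}

struct InjGroup {
  std::vector<int> pool;   // global neuron ids, axis-ordered
  std::vector<char> in_g;  // membership flags by pool position
  std::vector<int> g;      // pool positions currently designated
  bool use_nb;
  double nb_r, nb_p;
  bool ventral_high;
  // per-phase rule: 0 = off, 1 = fixed band, 2 = linear ramp
  std::vector<int> rule_type;
  std::vector<double> rule_p1, rule_p2;
};

// One negative-binomial draw mapped onto the pool axis; rejection-resampled
// until it lands inside [0, m).
static inline int nb_position(std::mt19937 &rng, const InjGroup &gr) {
  std::negative_binomial_distribution<int> nb((int)gr.nb_r, gr.nb_p);
  int m = (int)gr.pool.size();
  for (;;) {
    int x = nb(rng);
    if (x < m) return gr.ventral_high ? x : (m - 1 - x);
  }
}

// [[Rcpp::export]]
List engine_run(NumericVector a, NumericVector b, NumericVector c,
                NumericVector d, NumericVector v0, NumericVector u0,
                IntegerVector syn_ptr, IntegerVector syn_tgt,
                NumericVector syn_w, IntegerVector syn_delay, int n_steps,
                int phase_len,
                double amplitude, double perturb_fraction, List groups,
                int seed, bool record_spikes, double v_floor) {
  const int n = a.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  int d_max = 1;
  for (int k = 0; k < syn_delay.size(); ++k)
    if (syn_delay[k] > d_max) d_max = syn_delay[k];
  // ring buffer of future synaptic currents, slot (t % d_max)
  std::vector<std::vector<double> > Ibuf(d_max, std::vector<double>(n, 0.0));
  std::vector<double> I(n, 0.0);

  std::mt19937 rng((uint32_t)seed);

  const int n_groups = groups.size();
  std::vector<InjGroup> grs(n_groups);
  for (int gi = 0; gi < n_groups; ++gi) {
    List spec = groups[gi];
    IntegerVector pool = spec["pool"];
    IntegerVector ginit = spec["g_init"];  // pool positions, 0-based
    InjGroup &gr = grs[gi];
    gr.pool.assign(pool.begin(), pool.end());
    gr.in_g.assign(gr.pool.size(), 0);
    gr.g.assign(ginit.begin(), ginit.end());
    for (size_t j = 0; j < gr.g.size(); ++j) gr.in_g[gr.g[j]] = 1;
    gr.use_nb = as<bool>(spec["use_nb"]);
    gr.nb_r = as<double>(spec["nb_r"]);
    gr.nb_p = as<double>(spec["nb_p"]);
    gr.ventral_high = as<bool>(spec["ventral_high"]);
    IntegerVector rt = spec["rule_type"];
    NumericVector p1 = spec["rule_p1"], p2 = spec["rule_p2"];
    gr.rule_type.assign(rt.begin(), rt.end());
    gr.rule_p1.assign(p1.begin(), p1.end());
    gr.rule_p2.assign(p2.begin(), p2.end());
  }

  std::vector<int> spiked, new_pos;
  std::vector<int> spike_t, spike_id;
  IntegerMatrix inj_counts(n_steps, n_groups);

  for (int t = 1; t <= n_steps; ++t) {
    const int phase = (t - 1) / phase_len;  // 0-based phase index
    std::vector<double> &slot = Ibuf[t % d_max];
    I.swap(slot);
    std::fill(slot.begin(), slot.end(), 0.0);

    // --- injection protocol ---
    for (int gi = 0; gi < n_groups; ++gi) {
      InjGroup &gr = grs[gi];
      const int m = (int)gr.pool.size();
      const int gsz = (int)gr.g.size();
      // 1) perturb the designated set: swap out round(fraction * |g|)
      //    members for neurons outside the pre-perturbation set
      int k_swap = (int)std::lround(perturb_fraction * gsz);
      if (k_swap > 0) {
        for (int j = 0; j < k_swap; ++j) {
          int idx = j + runif_int(rng, gsz - j);
          std::swap(gr.g[j], gr.g[idx]);
        }
        new_pos.clear();
        while ((int)new_pos.size() < k_swap) {
          int pos = gr.use_nb ? nb_position(rng, gr) : runif_int(rng, m);
          if (!gr.in_g[pos]) {
            gr.in_g[pos] = 1;
            new_pos.push_back(pos);
          }
        }
        for (int j = 0; j < k_swap; ++j) {
          gr.in_g[gr.g[j]] = 0;
          gr.g[j] = new_pos[j];
        }
      }
      // 2) per-phase injected count
      int count = 0;
      const int rt = gr.rule_type[phase];
      if (rt == 1) {
        int lo = (int)std::floor(m * gr.rule_p1[phase]);
        int hi = (int)std::floor(m * gr.rule_p2[phase]);
        count = lo + runif_int(rng, hi - lo + 1);
      } else if (rt == 2) {
        double tp = (double)t / (double)phase_len;
        double from = gr.rule_p1[phase], to = gr.rule_p2[phase];
        // epsilon absorbs floating-point error before flooring
        count = (int)std::floor(
            m * ((to - from) * tp + from - (double)phase * (to - from)) +
            1e-6);
      }
      if (count > gsz) count = gsz;
      if (count < 0) count = 0;
      inj_counts(t - 1, gi) = count;
      // 3) uniform subset of the designated set receives the pulse
      for (int j = 0; j < count; ++j) {
        int idx = j + runif_int(rng, gsz - j);
        std::swap(gr.g[j], gr.g[idx]);
        I[gr.pool[gr.g[j]]] += amplitude;
      }
    }

    // --- Izhikevich update: two 0.5-ms half-steps for v, u once ---
    spiked.clear();
    for (int i = 0; i < n; ++i) {
      double vi = v[i], ui = u[i], Ii = I[i];
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      if (vi < v_floor) vi = v_floor;
      if (vi < 30.0)
        vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      if (vi < v_floor) vi = v_floor;
      if (vi > 30.0) vi = 30.0;
      ui += a[i] * (b[i] * vi - ui);
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("non-finite state for neuron %d at step %d", i + 1, t);
      if (vi >= 30.0) {
        spiked.push_back(i);
        v[i] = c[i];
        u[i] = ui + d[i];
      } else {
        v[i] = vi;
        u[i] = ui;
      }
    }
    // deposit synaptic currents of this step's spikes into future slots
    // (per-synapse delay >= 1 step)
    for (size_t s = 0; s < spiked.size(); ++s) {
      int src = spiked[s];
      for (int k = syn_ptr[src]; k < syn_ptr[src + 1]; ++k)
        Ibuf[(t + syn_delay[k]) % d_max][syn_tgt[k]] += syn_w[k];
    }
    if (record_spikes) {
      for (size_t s = 0; s < spiked.size(); ++s) {
        spike_t.push_back(t);
        spike_id.push_back(spiked[s] + 1);
      }
    }
  }

  return List::create(
      _["spike_time"] = IntegerVector(spike_t.begin(), spike_t.end()),
      _["spike_neuron"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["inj_counts"] = inj_counts,
      _["v"] = NumericVector(v.begin(), v.end()),
      _["u"] = NumericVector(u.begin(), u.end()));
}
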