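#include <Rcpp.h>
using namespace Rcpp;

// 1D loop-extrusion dynamics on a lattice of monomers.
//
// Each LEF has an upstream leg i and a downstream leg j (i < j). Per step,
// a free upstream leg moves i -> i-1 with probability step_prob unless the
// target is occupied by another leg or lies in a blocked region; the
// downstream leg mirrors this to j+1. A leg arriving on a CTCF site whose
// blocking orientation faces its direction of motion is captured with the
// site's capture probability and stays immobile until released
// (release_prob per step). Each LEF is unloaded with unload_prob per step
// and immediately reloaded at a uniformly random unoccupied adjacent pair,
// keeping the LEF count constant.
//
// ctcf_dir: +1 blocks right-moving (downstream) legs, -1 blocks
// left-moving (upstream) legs; orientation_agnostic makes every site block
// both directions. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List lef_simulate_cpp(int n_monomers, int n_lefs, int n_steps,
                      int sample_every,
                      double step_prob, double release_prob,
                      double unload_prob,
                      IntegerVector ctcf_pos, IntegerVector ctcf_dir,
                      NumericVector ctcf_p,
                      LogicalVector blocked,
                      bool orientation_agnostic,
                      int track_lo, int track_hi) {
  RNGScope scope;
  if (n_monomers < 2 * n_lefs + 2)
    stop("lattice too small to place the requested number of LEFs");

  std::vector<int> occ(n_monomers, -1);          // leg occupancy: lef id or -1
  std::vector<double> cap_left(n_monomers, 0.0);  // capture prob for left-movers
  std::vector<double> cap_right(n_monomers, 0.0); // capture prob for right-movers
  std::vector<bool> blk(n_monomers, false);
  for (int k = 0; k < blocked.size(); ++k) blk[k] = blocked[k];
  for (int k = 0; k < ctcf_pos.size(); ++k) {
    int p = ctcf_pos[k];
    if (p < 0 || p >= n_monomers) stop("CTCF position outside lattice");
    if (orientation_agnostic || ctcf_dir[k] < 0) cap_left[p] = ctcf_p[k];
    if (orientation_agnostic || ctcf_dir[k] > 0) cap_right[p] = ctcf_p[k];
  }

  std::vector<int> li(n_lefs), lj(n_lefs);
  std::vector<bool> ci(n_lefs, false), cj(n_lefs, false); // captured flags
  std::vector<int> cap_step_i(n_lefs, -1), cap_step_j(n_lefs, -1);
  std::vector<int> load_i(n_lefs), load_j(n_lefs);
  // traversal bookkeeping: was the leg loaded outside [track_lo, track_hi)?
  bool tracking = track_lo >= 0 && track_hi > track_lo;
  long n_candidate = 0, n_crossed = 0;
  std::vector<bool> cand_i(n_lefs, false), cand_j(n_lefs, false);
  std::vector<bool> crossed_i(n_lefs, false), crossed_j(n_lefs, false);

  auto load_lef = [&](int id) {
    for (int tries = 0; tries < 100000; ++tries) {
      int p = (int)std::floor(unif_rand() * (n_monomers - 1));
      if (p < 0) p = 0;
      if (p >= n_monomers - 1) p = n_monomers - 2;
      if (occ[p] >= 0 || occ[p + 1] >= 0 || blk[p] || blk[p + 1]) continue;
      li[id] = p; lj[id] = p + 1;
      occ[p] = id; occ[p + 1] = id;
      ci[id] = cj[id] = false;
      load_i[id] = p; load_j[id] = p + 1;
      if (tracking) {
        bool out_i = p < track_lo || p >= track_hi;
        bool out_j = (p + 1) < track_lo || (p + 1) >= track_hi;
        cand_i[id] = out_i; cand_j[id] = out_j;
        crossed_i[id] = crossed_j[id] = false;
        n_candidate += (out_i ? 1 : 0) + (out_j ? 1 : 0);
      }
      return;
    }
    stop("could not place LEF on lattice");
  };

  auto finish_leg = [&](bool cand, bool crossed) {
    if (tracking && cand && crossed) n_crossed += 1;
  };

  for (int id = 0; id < n_lefs; ++id) load_lef(id);

  int n_samples = n_steps / sample_every;
  IntegerMatrix samp_i(n_samples, n_lefs), samp_j(n_samples, n_lefs);
  LogicalMatrix samp_ci(n_samples, n_lefs), samp_cj(n_samples, n_lefs);
  std::vector<double> dwells;
  std::vector<double> censored; // capture episodes cut short by unloading
  int occupancy_violations = 0;
  int srow = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int id = 0; id < n_lefs; ++id) {
      // unload / immediate reload
      if (unif_rand() < unload_prob) {
        if (ci[id]) censored.push_back(step - cap_step_i[id]);
        if (cj[id]) censored.push_back(step - cap_step_j[id]);
        finish_leg(cand_i[id], crossed_i[id]);
        finish_leg(cand_j[id], crossed_j[id]);
        occ[li[id]] = -1; occ[lj[id]] = -1;
        load_lef(id);
        continue;
      }
      // upstream leg (moves left)
      if (ci[id]) {
        if (unif_rand() < release_prob) {
          dwells.push_back(step - cap_step_i[id]);
          ci[id] = false;
        }
      } else if (unif_rand() < step_prob) {
        int t = li[id] - 1;
        if (t >= 0 && occ[t] < 0 && !blk[t]) {
          occ[li[id]] = -1;
          li[id] = t;
          occ[t] = id;
          if (cap_left[t] > 0 && unif_rand() < cap_left[t]) {
            ci[id] = true;
            cap_step_i[id] = step;
          }
          if (tracking && cand_i[id] && load_i[id] >= track_hi && t < track_lo)
            crossed_i[id] = true;
        }
      }
      // downstream leg (moves right)
      if (cj[id]) {
        if (unif_rand() < release_prob) {
          dwells.push_back(step - cap_step_j[id]);
          cj[id] = false;
        }
      } else if (unif_rand() < step_prob) {
        int t = lj[id] + 1;
        if (t < n_monomers && occ[t] < 0 && !blk[t]) {
          occ[lj[id]] = -1;
          lj[id] = t;
          occ[t] = id;
          if (cap_right[t] > 0 && unif_rand() < cap_right[t]) {
            cj[id] = true;
            cap_step_j[id] = step;
          }
          if (tracking && cand_j[id] && load_j[id] < track_lo && t >= track_hi)
            crossed_j[id] = true;
        }
      }
    }
    if (step % sample_every == 0 && srow < n_samples) {
      for (int id = 0; id < n_lefs; ++id) {
        samp_i(srow, id) = li[id];
        samp_j(srow, id) = lj[id];
        samp_ci(srow, id) = ci[id];
        samp_cj(srow, id) = cj[id];
        if (li[id] >= lj[id]) occupancy_violations += 1;
      }
      // full occupancy audit on sampled steps
      std::vector<int> seen(n_monomers, 0);
      for (int id = 0; id < n_lefs; ++id) {
        if (++seen[li[id]] > 1) occupancy_violations += 1;
        if (++seen[lj[id]] > 1) occupancy_violations += 1;
      }
      ++srow;
    }
  }
  // close out traversal bookkeeping for legs alive at the end
  for (int id = 0; id < n_lefs; ++id) {
    finish_leg(cand_i[id], crossed_i[id]);
    finish_leg(cand_j[id], crossed_j[id]);
  }

  return List::create(
    _["i"] = samp_i, _["j"] = samp_j,
    _["captured_i"] = samp_ci, _["captured_j"] = samp_cj,
    _["dwells"] = NumericVector(dwells.begin(), dwells.end()),
    _["censored_dwells"] = NumericVector(censored.begin(), censored.end()),
    _["occupancy_violations"] = occupancy_violations,
    _["n_candidate_legs"] = (double)n_candidate,
    _["n_crossed_legs"] = (double)n_crossed);
}
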