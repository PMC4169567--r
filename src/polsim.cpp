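#include <Rcpp.h>
#include <map>
#include <vector>

using namespace Rcpp;

// Deterministic RNA polymerase traffic on a single gene.
//
// Discrete time, 1 unit per step. A polymerase occupies one base pair and
// spends 1 time unit per position (v base pairs per unit when moving), except
// at a pause site where it dwells max(dt_i, 1) units. A new polymerase enters
// at position 1 every dtau units; if position 1 is occupied the attempt is
// recorded as an initiation releasing a length-0 transcript. Within a step,
// polymerases advance from the most 3' to the most 5' (no same-step
// pass-through), then initiation is attempted. A polymerase whose path is
// blocked by the one ahead terminates immediately, releasing the transcript
// synthesized up to the base behind the blocker; reaching position L releases
// a full-length transcript.
//
// [[Rcpp::export(name = ".polsim_run")]]
List polsim_run(int L, IntegerVector pause_pos, IntegerVector pause_dwell,
                int dtau, int v, int T, int burn_in,
                int stop_after_full = -1) {
  int n_pause = pause_pos.size();
  // effective dwell at a pause is at least the default 1-unit waiting time
  std::vector<int> pdwell(n_pause);
  for (int i = 0; i < n_pause; ++i)
    pdwell[i] = pause_dwell[i] > 1 ? pause_dwell[i] : 1;

  // active polymerases, ordered most 3' (front) to most 5' (back)
  std::vector<int> pos, dwell;
  pos.reserve(256); dwell.reserve(256);

  long initiations = 0, full_count = 0;
  long init_post = 0, full_post = 0, trunc_post = 0;
  std::map<int, long> trunc; // transcript length -> count, whole run
  int first_full_time = NA_INTEGER;
  int t_end = T;

  // dwell units for a polymerase landing on `p`
  auto dwell_at = [&](int p) {
    for (int i = 0; i < n_pause; ++i)
      if (pause_pos[i] == p) return pdwell[i];
    return 1;
  };
  // first pause strictly beyond `p`, capped at p + v; 0 if none in range
  auto pause_in_path = [&](int p) {
    for (int i = 0; i < n_pause; ++i)
      if (pause_pos[i] > p && pause_pos[i] <= p + v) return (int)pause_pos[i];
    return 0;
  };

  std::vector<int> npos, ndwell;
  for (int t = 1; t <= T; ++t) {
    npos.clear(); ndwell.clear();
    int ahead = L + 1; // position of nearest kept downstream polymerase
    for (size_t i = 0; i < pos.size(); ++i) {
      int d = dwell[i] - 1;
      if (d > 0) { // still dwelling at its position
        npos.push_back(pos[i]); ndwell.push_back(d);
        ahead = pos[i];
        continue;
      }
      int target = pos[i] + v;
      int pp = pause_in_path(pos[i]);
      if (pp) target = pp;
      if (target >= ahead) {
        // blocked: release the transcript synthesized up to the base behind
        int len = ahead - 1;
        ++trunc[len];
        if (t > burn_in) ++trunc_post;
      } else if (target >= L) {
        ++full_count;
        if (t > burn_in) ++full_post;
        if (first_full_time == NA_INTEGER) first_full_time = t;
      } else {
        npos.push_back(target);
        ndwell.push_back(dwell_at(target));
        ahead = target;
      }
    }
    pos.swap(npos); dwell.swap(ndwell);

    if ((t - 1) % dtau == 0) { // initiation attempt
      ++initiations;
      if (t > burn_in) ++init_post;
      bool occupied = !pos.empty() && pos.back() == 1;
      if (occupied) {
        ++trunc[0];
        if (t > burn_in) ++trunc_post;
      } else {
        pos.push_back(1);
        dwell.push_back(dwell_at(1));
      }
    }

    if (stop_after_full > 0 && full_post >= stop_after_full) {
      t_end = t;
      break;
    }
  }

  long trunc_total = 0;
  IntegerVector tl(trunc.size());
  NumericVector tc(trunc.size());
  int k = 0;
  for (auto &kv : trunc) {
    tl[k] = kv.first;
    tc[k] = (double)kv.second;
    trunc_total += kv.second;
    ++k;
  }

  return List::create(
    _["initiations"] = (double)initiations,
    _["full_length_count"] = (double)full_count,
    _["truncated_total"] = (double)trunc_total,
    _["truncated_lengths"] = tl,
    _["truncated_counts"] = tc,
    _["in_progress"] = (double)pos.size(),
    _["first_full_release_time"] = first_full_time,
    _["t_end"] = t_end,
    _["post"] = List::create(
      _["initiations"] = (double)init_post,
      _["full_length"] = (double)full_post,
      _["truncated"] = (double)trunc_post,
      _["window"] = (double)(t_end - burn_in))
  );
}
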