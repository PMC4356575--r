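#include <Rcpp.h>
using namespace Rcpp;

// Fast reimplementation of the daily dynamics. States: 1 = C, 0 = D.
// Majority: +1 cooperator majority, -1 defector majority, 0 tie.
// Uses R's RNG (unif_rand) so set.seed() controls whole runs.
//
// Draw order per focal agent: focal transition draw (where the rule
// table has a 50% cell), then event-emission draws, then event-response
// draws, in emission order. No draw is consumed when no change is
// possible (matches the R rule functions).

namespace {

struct Params { double h; int d; };

inline int rint(int n) {               // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;           // guard the unif_rand()==1 edge
}

inline void police(int t, int &st, int &tm, int maj, const Params &p) {
  if (t == 2 || t == 3 || t == 7) return;
  if (st == 1 && tm == 0) return;      // voluntary C: never downgraded
  if (t == 5 && maj != 1) return;
  if (unif_rand() < p.h) { st = 1; tm = p.d; }
}

inline void offer(int t, int &st, int &tm, int maj, const Params &p) {
  if (t == 1 || t == 2 || t == 3 || t == 7) return;
  if (st == 1 && tm == 0) return;
  if (t == 4) { st = 1; tm = p.d; }
  else if (t == 5) { if (maj == 1) { st = 1; tm = 0; } }
  else if (t == 6) { if (unif_rand() < 0.5) { st = 1; tm = 0; } }
}

inline void tempt(int t, int &st, int &tm, int maj) {
  if (t == 2 || t == 3 || t == 7 || st == 0) return;
  if (t == 1 || t == 4) { st = 0; tm = 0; }
  else if (t == 5) { if (maj == -1) { st = 0; tm = 0; } }
  else if (t == 6) { if (unif_rand() < 0.5) { st = 0; tm = 0; } }
}

} // namespace

// [[Rcpp::export(name = ".run_sim_cpp")]]
List run_sim_cpp(IntegerVector type, IntegerVector state0,
                 IntegerVector timer0, double h, int d, int n_days) {
  const int n = type.size();
  Params p{h, d};
  std::vector<int> tp(type.begin(), type.end());
  std::vector<int> st(state0.begin(), state0.end());
  std::vector<int> tm(timer0.begin(), timer0.end());
  std::vector<int> perm(n);

  IntegerMatrix coop(n_days + 1, 7);   // cooperators per type per day
  IntegerVector typeCount(7);
  for (int i = 0; i < n; ++i) typeCount[tp[i] - 1]++;

  int prevCoop = 0;
  for (int i = 0; i < n; ++i) {
    if (st[i] == 1) { coop(0, tp[i] - 1)++; prevCoop++; }
  }

  for (int day = 1; day <= n_days; ++day) {
    int maj = (2 * prevCoop > n) ? 1 : (2 * prevCoop < n ? -1 : 0);

    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {           // Fisher-Yates shuffle
      int j = rint(i + 1);
      std::swap(perm[i], perm[j]);
    }

    for (int k = 0; k < n; ++k) {
      int f = perm[k];
      int q = rint(n - 1);                      // partner among others
      if (q >= f) ++q;
      int t = tp[f], s = st[f], ps = st[q];

      switch (t) {
      case 1:
        if (s == 1 && ps == 0) { st[f] = 0; tm[f] = 0; }
        else if (s == 0 && ps == 1) tempt(tp[q], st[q], tm[q], maj);
        break;
      case 2:
        if (ps == 0) {
          bool do_police = unif_rand() < 0.5;   // emission draw
          offer(tp[q], st[q], tm[q], maj, p);
          if (do_police) police(tp[q], st[q], tm[q], maj, p);
        }
        break;
      case 3:
        if (ps == 0 && unif_rand() < 0.5) offer(tp[q], st[q], tm[q], maj, p);
        break;
      case 4:
        if (s == 1 && ps == 0) { st[f] = 0; tm[f] = 0; }
        else if (s == 0 && ps == 1) { st[f] = 1; tm[f] = p.d; }
        break;
      case 5:
        if (s == 1 && ps == 0) { if (maj == -1) { st[f] = 0; tm[f] = 0; } }
        else if (s == 0 && ps == 1) { if (maj == 1) { st[f] = 1; tm[f] = 0; } }
        break;
      case 6:
        if (s == 1 && ps == 0) {
          if (unif_rand() < 0.5) { st[f] = 0; tm[f] = 0; }
        } else if (s == 0 && ps == 1) {
          if (unif_rand() < 0.5) { st[f] = 1; tm[f] = 0; }
        }
        break;
      case 7:
        if (ps == 0) police(tp[q], st[q], tm[q], maj, p);
        break;
      }
    }

    int dayCoop = 0;
    for (int i = 0; i < n; ++i) {               // end-of-day timer expiry
      if (tm[i] > 0 && --tm[i] == 0) st[i] = 0;
      if (st[i] == 1) { coop(day, tp[i] - 1)++; dayCoop++; }
    }
    prevCoop = dayCoop;
  }

  return List::create(_["coop_by_type"] = coop,
                      _["type_counts"] = typeCount,
                      _["final_state"] = IntegerVector(st.begin(), st.end()),
                      _["final_timer"] = IntegerVector(tm.begin(), tm.end()));
}
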