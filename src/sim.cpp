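#include <Rcpp.h>
using namespace Rcpp;

// Softmax choice probability for option 1 of two, written as a logistic of
// the attraction difference so it is stable for any lambda * gap.
static inline double p_option1(double a1, double a2, double lam) {
  return 1.0 / (1.0 + std::exp(-lam * (a1 - a2)));
}

// Online applied-criterion tracker: >= 17 correct in the most recent
// min(n, 20) completed trials. Returns the finish trial (1-based, counted
// in completed trials) or 0 while unmet.
struct CriterionTracker {
  int buf[20];
  int n, wsum;
  CriterionTracker() : n(0), wsum(0) { for (int i = 0; i < 20; ++i) buf[i] = 0; }
  // returns true if the criterion is met after recording this flag
  bool push(int correct) {
    int idx = n % 20;
    if (n >= 20) wsum -= buf[idx];
    buf[idx] = correct;
    wsum += correct;
    ++n;
    return n >= 17 && wsum >= 17;
  }
};

//' @noRd
// [[Rcpp::export]]
List simulate_agent_cpp(double phi1, double lam1, double phi2, double lam2,
                        double payoff, double a0, int max_trials,
                        bool stop_at_criterion, int extra1, int extra2) {
  std::vector<int> choice, correct, phase;
  std::vector<double> reward;
  double A[2] = {a0, a0};
  double phi[2] = {phi1, phi2};
  double lam[2] = {lam1, lam2};
  int extra[2] = {extra1, extra2};
  IntegerVector finish(2, NA_INTEGER);
  IntegerVector ntr(2);

  for (int ph = 0; ph < 2; ++ph) {
    int rewarded = ph;  // option 1 pays in initial learning, option 2 after
    CriterionTracker crit;
    int t = 0, fin = 0, todo_extra = -1;
    while (t < max_trials) {
      ++t;
      double p1 = p_option1(A[0], A[1], lam[ph]);
      int ch = (unif_rand() < p1) ? 0 : 1;
      int corr = (ch == rewarded) ? 1 : 0;
      double pay = corr ? payoff : 0.0;
      A[ch] = (1.0 - phi[ph]) * A[ch] + phi[ph] * pay;
      choice.push_back(ch + 1);
      correct.push_back(corr);
      reward.push_back(pay);
      phase.push_back(ph + 1);
      if (fin == 0 && crit.push(corr)) fin = t;
      if (fin > 0 && stop_at_criterion) {
        if (todo_extra < 0) todo_extra = extra[ph];
        if (todo_extra-- == 0) break;
      }
    }
    finish[ph] = (fin > 0) ? fin : NA_INTEGER;
    ntr[ph] = t;
  }

  return List::create(
    _["choice"] = wrap(choice), _["correct"] = wrap(correct),
    _["reward"] = wrap(reward), _["phase"] = wrap(phase),
    _["finish"] = finish, _["n_trials"] = ntr);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector lifetime_fitness_cpp(NumericVector phi, NumericVector lam,
                                   double u, double s, int t_total,
                                   int fitness_window, double payoff,
                                   bool reward_swap) {
  int n = phi.size();
  IntegerVector fitness(n);
  for (int i = 0; i < n; ++i) {
    double A[2] = {0.0, 0.0};
    int optimal = (unif_rand() < 0.5) ? 0 : 1;
    int fit = 0;
    for (int t = 0; t < t_total; ++t) {
      if (unif_rand() < u) optimal = 1 - optimal;
      double p1 = p_option1(A[0], A[1], lam[i]);
      int ch = (unif_rand() < p1) ? 0 : 1;
      bool fail = (s > 0.0) && (unif_rand() < s);
      int rewarded_opt;
      if (fail) rewarded_opt = reward_swap ? (1 - optimal) : -1;
      else rewarded_opt = optimal;
      double pay = (ch == rewarded_opt) ? payoff : 0.0;
      A[ch] = (1.0 - phi[i]) * A[ch] + phi[i] * pay;
      if (t >= t_total - fitness_window && pay > 0.0) ++fit;
    }
    fitness[i] = fit;
  }
  return fitness;
}
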