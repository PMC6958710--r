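// Simulation engine: exact Gillespie SSA for the five built-in
// host-parasite models and the paired-update discrete-time processes.
// Model ids: 1 EcoEvo, 2 EcoEvoPlus, 3 Hybrid, 4 Evo, 5 EvoPlus
// (dt ids: 1 dtEvoPlus, 2 dtEvo).
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// categorical draw proportional to w, u ~ U(0, sum(w))
static int pick_prop(const std::vector<double>& w, double u) {
  double acc = 0.0;
  int last = -1;
  for (size_t i = 0; i < w.size(); ++i) {
    if (w[i] <= 0.0) continue;
    acc += w[i];
    last = (int)i;
    if (u <= acc) return (int)i;
  }
  return last;  // numerical slack: return last positive channel
}

// [[Rcpp::export]]
List cpp_simulate_dt(int model_id, double H1, double N_H, double P1,
                     double N_P, double w_H, double w_P, double alpha,
                     double beta, double max_steps, int record_stride) {
  std::vector<double> rec_steps, rec_H1, rec_P1;
  double step = 0.0;
  long long step_i = 0;
  int ext_species = 0, ext_genotype = 0;
  bool censored = false, found = false;

  auto check_loss = [&]() {
    if (found) return;
    if (H1 <= 0)        { ext_species = 1; ext_genotype = 1; found = true; }
    else if (H1 >= N_H) { ext_species = 1; ext_genotype = 2; found = true; }
    else if (P1 <= 0)   { ext_species = 2; ext_genotype = 1; found = true; }
    else if (P1 >= N_P) { ext_species = 2; ext_genotype = 2; found = true; }
  };

  auto record = [&]() {
    rec_steps.push_back(step);
    rec_H1.push_back(H1);
    rec_P1.push_back(P1);
  };

  if (record_stride > 0) record();
  check_loss();

  while (!found) {
    if (step >= max_steps) { censored = true; break; }

    double h1 = H1 / N_H, p1 = P1 / N_P;
    double piH1 = (alpha + beta) - (alpha * p1 + beta * (1.0 - p1));
    double piH2 = (alpha + beta) - (alpha * (1.0 - p1) + beta * p1);
    double fH1 = 1.0 - w_H + w_H * piH1, fH2 = 1.0 - w_H + w_H * piH2;
    double piP1 = alpha * h1 + beta * (1.0 - h1);
    double piP2 = alpha * (1.0 - h1) + beta * h1;
    double fP1 = 1.0 - w_P + w_P * piP1, fP2 = 1.0 - w_P + w_P * piP2;

    double up_h = 0.0, dn_h = 0.0, up_p = 0.0, dn_p = 0.0;
    double xy = h1 * (1.0 - h1);
    if (xy > 0.0) {
      if (model_id == 1) {                       // Moran (dtEvoPlus)
        double fbar = h1 * fH1 + (1.0 - h1) * fH2;
        up_h = xy * fH1 / fbar;
        dn_h = xy * fH2 / fbar;
      } else {                                    // pairwise comparison
        double denom = alpha - beta;
        double term = (denom <= 0.0 || fH1 == fH2)
                        ? 0.5 : 0.5 + 0.5 * (fH1 - fH2) / denom;
        up_h = xy * term;
        dn_h = xy * (1.0 - term);
      }
    }
    xy = p1 * (1.0 - p1);
    if (xy > 0.0) {
      if (model_id == 1) {
        double fbar = p1 * fP1 + (1.0 - p1) * fP2;
        up_p = xy * fP1 / fbar;
        dn_p = xy * fP2 / fbar;
      } else {
        double denom = alpha - beta;
        double term = (denom <= 0.0 || fP1 == fP2)
                        ? 0.5 : 0.5 + 0.5 * (fP1 - fP2) / denom;
        up_p = xy * term;
        dn_p = xy * (1.0 - term);
      }
    }

    // simultaneous update: both draws use the pre-step state
    double u = unif_rand();
    double dH = (u < up_h) ? 1.0 : ((u < up_h + dn_h) ? -1.0 : 0.0);
    u = unif_rand();
    double dP = (u < up_p) ? 1.0 : ((u < up_p + dn_p) ? -1.0 : 0.0);
    H1 += dH;
    P1 += dP;
    step += 1.0;
    ++step_i;

    if (record_stride > 0 && step_i % record_stride == 0) record();
    check_loss();
  }

  if (record_stride > 0 &&
      (rec_steps.empty() || rec_steps.back() != step)) record();

  return List::create(
    _["steps"] = step, _["censored"] = censored,
    _["ext_species"] = ext_species, _["ext_genotype"] = ext_genotype,
    _["rec_steps"] = rec_steps, _["rec_H1"] = rec_H1, _["rec_P1"] = rec_P1);
}

// [[Rcpp::export]]
List cpp_simulate_ct(int model_id, NumericVector H0, NumericVector P0,
                     double w_H, double w_P, double alpha, double beta,
                     double b_H, double d_P, double lam, double comp_rate,
                     double mut_H, double mut_P, bool with_mutation,
                     double t_max, double event_max, double n_max,
                     bool stop_on_loss, NumericVector grid) {
  const int n = H0.size();
  std::vector<double> H(H0.begin(), H0.end());
  std::vector<double> P(P0.begin(), P0.end());
  double NH = 0.0, NP = 0.0;
  for (int i = 0; i < n; ++i) { NH += H[i]; NP += P[i]; }

  double t = 0.0, n_events = 0.0;
  bool censored = false, absorbed = false;

  // extinction record (first time any genotype count is zero)
  bool ext_found = false;
  double ext_time = NA_REAL;
  int ext_species = 0, ext_genotype = 0;
  auto note_loss = [&](int species, int geno, double when) {
    if (ext_found) return;
    ext_found = true;
    ext_time = when;
    ext_species = species;
    ext_genotype = geno + 1;
  };
  for (int i = 0; i < n && !ext_found; ++i) if (H[i] <= 0) note_loss(1, i, 0.0);
  for (int i = 0; i < n && !ext_found; ++i) if (P[i] <= 0) note_loss(2, i, 0.0);

  // revival log (a count leaving zero; only possible with mutation)
  std::vector<double> rev_t;
  std::vector<int> rev_species, rev_genotype;

  // grid recording (state held at each grid time)
  const int G = grid.size();
  int g = 0;
  NumericVector rec_t(G);
  NumericMatrix rec_H(G, n), rec_P(G, n);
  auto record_upto = [&](double limit) {
    while (g < G && grid[g] <= limit) {
      rec_t[g] = grid[g];
      for (int i = 0; i < n; ++i) { rec_H(g, i) = H[i]; rec_P(g, i) = P[i]; }
      ++g;
    }
  };

  std::vector<double> work(n), cat(7);
  bool stopped_by_loss = stop_on_loss && ext_found;

  while (!stopped_by_loss) {
    if (NH + NP > n_max) { censored = true; break; }
    if (n_events >= event_max) { censored = true; break; }

    // ---- total rate by category ---------------------------------------
    double total = 0.0;
    std::fill(cat.begin(), cat.end(), 0.0);
    double sumHD = 0.0, sumPB = 0.0;  // Hybrid totals
    double r_up_h = 0.0, r_dn_h = 0.0, r_up_p = 0.0, r_dn_p = 0.0;

    if (model_id == 1 || model_id == 2) {       // EcoEvo(+)
      double inter = 0.0;
      for (int i = 0; i < n; ++i) inter += H[i] * P[i];
      cat[0] = b_H * NH;                        // host birth
      cat[1] = d_P * NP;                        // parasite death
      cat[2] = lam * inter;                     // matched host death
      cat[3] = lam * inter;                     // matched parasite birth
      cat[4] = (model_id == 2) ? comp_rate * NH * NH : 0.0;
    } else if (model_id == 3) {                 // Hybrid
      for (int i = 0; i < n; ++i) {
        double dH_i = (NP > 0)
          ? 1.0 - w_H + w_H * (alpha * P[i] + beta * (NP - P[i])) / NP
          : 1.0 - w_H;
        double bP_i = (NH > 0)
          ? 1.0 - w_P + w_P * (alpha * H[i] + beta * (NH - H[i])) / NH
          : 1.0 - w_P;
        sumHD += H[i] * dH_i;
        sumPB += P[i] * bP_i;
      }
      cat[0] = sumHD;                           // host death
      cat[1] = sumPB;                           // parasite birth
      cat[2] = (NH > 0) ? sumHD : 0.0;          // balancing host birth
      cat[3] = (NP > 0) ? sumPB : 0.0;          // balancing parasite death
    } else {                                    // Evo / EvoPlus, n = 2
      double p1 = (NP > 0) ? P[0] / NP : 0.0;
      double h1 = (NH > 0) ? H[0] / NH : 0.0;
      double fH1 = 1.0 - w_H +
        w_H * ((alpha + beta) - (alpha * p1 + beta * (1.0 - p1)));
      double fH2 = 1.0 - w_H +
        w_H * ((alpha + beta) - (alpha * (1.0 - p1) + beta * p1));
      double fP1 = 1.0 - w_P + w_P * (alpha * h1 + beta * (1.0 - h1));
      double fP2 = 1.0 - w_P + w_P * (alpha * (1.0 - h1) + beta * h1);
      if (H[0] > 0 && H[1] > 0) {
        double xy = h1 * (1.0 - h1);
        if (model_id == 5) {
          double fbar = h1 * fH1 + (1.0 - h1) * fH2;
          r_up_h = xy * fH1 / fbar;
          r_dn_h = xy * fH2 / fbar;
        } else {
          double denom = alpha - beta;
          double term = (denom <= 0.0 || fH1 == fH2)
                          ? 0.5 : 0.5 + 0.5 * (fH1 - fH2) / denom;
          r_up_h = xy * term;
          r_dn_h = xy * (1.0 - term);
        }
      }
      if (P[0] > 0 && P[1] > 0) {
        double xy = p1 * (1.0 - p1);
        if (model_id == 5) {
          double fbar = p1 * fP1 + (1.0 - p1) * fP2;
          r_up_p = xy * fP1 / fbar;
          r_dn_p = xy * fP2 / fbar;
        } else {
          double denom = alpha - beta;
          double term = (denom <= 0.0 || fP1 == fP2)
                          ? 0.5 : 0.5 + 0.5 * (fP1 - fP2) / denom;
          r_up_p = xy * term;
          r_dn_p = xy * (1.0 - term);
        }
      }
      cat[0] = r_up_h; cat[1] = r_dn_h; cat[2] = r_up_p; cat[3] = r_dn_p;
    }
    if (with_mutation) {
      cat[5] = mut_H * NH;
      cat[6] = mut_P * NP;
    }
    for (int c = 0; c < 7; ++c) total += cat[c];

    if (total <= 0.0) {                          // absorbing state
      absorbed = true;
      record_upto(grid.size() ? grid[G - 1] : t);  // state persists forever
      break;
    }

    double dt = exp_rand() / total;
    double t_new = t + dt;
    if (t_new > t_max) {                         // censored at the time cap
      record_upto(t_max);
      t = t_max;
      censored = true;
      break;
    }
    record_upto(std::nextafter(t_new, 0.0));     // grid points before event

    // ---- choose category, then genotype -------------------------------
    double u = unif_rand() * total;
    int c = 0;
    {
      double acc = 0.0;
      for (; c < 7; ++c) {
        if (cat[c] <= 0.0) continue;
        acc += cat[c];
        if (u <= acc) break;
      }
      if (c >= 7) c = 6;
    }

    int geno = 0, species = 0, delta = 0;   // species 1 host, 2 parasite
    int geno2 = -1, delta2 = 0;             // second change (replacement/mutation)
    double uu = unif_rand();

    if (model_id == 1 || model_id == 2) {
      switch (c) {
      case 0:  // host birth, prop to H_i
        for (int i = 0; i < n; ++i) work[i] = H[i];
        geno = pick_prop(work, uu * NH);
        species = 1; delta = 1; break;
      case 1:  // parasite death, prop to P_i
        for (int i = 0; i < n; ++i) work[i] = P[i];
        geno = pick_prop(work, uu * NP);
        species = 2; delta = -1; break;
      case 2:  // matched host death, prop to H_i P_i
        for (int i = 0; i < n; ++i) work[i] = H[i] * P[i];
        geno = pick_prop(work, uu * cat[2] / lam);
        species = 1; delta = -1; break;
      case 3:  // matched parasite birth, prop to H_i P_i
        for (int i = 0; i < n; ++i) work[i] = H[i] * P[i];
        geno = pick_prop(work, uu * cat[3] / lam);
        species = 2; delta = 1; break;
      case 4:  // competition death, prop to H_i
        for (int i = 0; i < n; ++i) work[i] = H[i];
        geno = pick_prop(work, uu * NH);
        species = 1; delta = -1; break;
      }
    } else if (model_id == 3) {
      switch (c) {
      case 0:  // host death, prop to H_i d_H,i
        for (int i = 0; i < n; ++i) {
          double dH_i = (NP > 0)
            ? 1.0 - w_H + w_H * (alpha * P[i] + beta * (NP - P[i])) / NP
            : 1.0 - w_H;
          work[i] = H[i] * dH_i;
        }
        geno = pick_prop(work, uu * cat[0]);
        species = 1; delta = -1; break;
      case 1:  // parasite birth, prop to P_i b_P,i
        for (int i = 0; i < n; ++i) {
          double bP_i = (NH > 0)
            ? 1.0 - w_P + w_P * (alpha * H[i] + beta * (NH - H[i])) / NH
            : 1.0 - w_P;
          work[i] = P[i] * bP_i;
        }
        geno = pick_prop(work, uu * cat[1]);
        species = 2; delta = 1; break;
      case 2:  // balancing host birth, uniform per capita
        for (int i = 0; i < n; ++i) work[i] = H[i];
        geno = pick_prop(work, uu * NH);
        species = 1; delta = 1; break;
      case 3:  // balancing parasite death, uniform per capita
        for (int i = 0; i < n; ++i) work[i] = P[i];
        geno = pick_prop(work, uu * NP);
        species = 2; delta = -1; break;
      }
    } else {  // Evo / EvoPlus replacement events
      switch (c) {
      case 0: species = 1; geno = 0; delta = 1;  geno2 = 1; delta2 = -1; break;
      case 1: species = 1; geno = 1; delta = 1;  geno2 = 0; delta2 = -1; break;
      case 2: species = 2; geno = 0; delta = 1;  geno2 = 1; delta2 = -1; break;
      case 3: species = 2; geno = 1; delta = 1;  geno2 = 0; delta2 = -1; break;
      }
    }
    if (c == 5) {  // host mutation, prop to H_i, then cyclic direction
      for (int i = 0; i < n; ++i) work[i] = H[i];
      geno = pick_prop(work, uu * NH);
      species = 1; delta = -1;
      geno2 = (unif_rand() < 0.5) ? (geno + 1) % n : (geno + n - 1) % n;
      delta2 = 1;
    } else if (c == 6) {  // parasite mutation
      for (int i = 0; i < n; ++i) work[i] = P[i];
      geno = pick_prop(work, uu * NP);
      species = 2; delta = -1;
      geno2 = (unif_rand() < 0.5) ? (geno + 1) % n : (geno + n - 1) % n;
      delta2 = 1;
    }

    // ---- apply ---------------------------------------------------------
    t = t_new;
    n_events += 1.0;
    std::vector<double>& X = (species == 1) ? H : P;
    double& NX = (species == 1) ? NH : NP;
    double before = X[geno];
    X[geno] += delta;
    NX += delta;
    if (delta > 0 && before == 0.0) {
      rev_t.push_back(t); rev_species.push_back(species);
      rev_genotype.push_back(geno + 1);
    }
    if (delta < 0 && X[geno] <= 0.0) note_loss(species, geno, t);
    if (geno2 >= 0) {
      double before2 = X[geno2];
      X[geno2] += delta2;
      NX += delta2;
      if (delta2 > 0 && before2 == 0.0) {
        rev_t.push_back(t); rev_species.push_back(species);
        rev_genotype.push_back(geno2 + 1);
      }
      if (delta2 < 0 && X[geno2] <= 0.0) note_loss(species, geno2, t);
    }
    stopped_by_loss = stop_on_loss && ext_found;
    if (stopped_by_loss) record_upto(t);
  }

  int n_rec = g;
  return List::create(
    _["t"] = t, _["n_events"] = n_events,
    _["H"] = NumericVector(H.begin(), H.end()),
    _["P"] = NumericVector(P.begin(), P.end()),
    _["censored"] = censored, _["absorbed"] = absorbed,
    _["ext_found"] = ext_found, _["ext_time"] = ext_time,
    _["ext_species"] = ext_species, _["ext_genotype"] = ext_genotype,
    _["n_rec"] = n_rec,
    _["rec_t"] = rec_t, _["rec_H"] = rec_H, _["rec_P"] = rec_P,
    _["rev_t"] = NumericVector(rev_t.begin(), rev_t.end()),
    _["rev_species"] = IntegerVector(rev_species.begin(), rev_species.end()),
    _["rev_genotype"] = IntegerVector(rev_genotype.begin(), rev_genotype.end()));
}
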