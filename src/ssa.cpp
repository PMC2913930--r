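// Exact Gillespie direct-method simulation of the ten-channel reaction
// network equivalent to the feedback-loop ODEs (release convention).
// Counts are integers held in doubles; omega converts nM to molecules.
//
// Channel order (matches build_reactions()):
//  0 p53 production            +p            sigma*omega
//  1 p53 removal               -p            alpha*n_p
//  2 complex formation         -p -m +c      kf/omega*n_p*n_m
//  3 complex dissociation      +p +m -c      kb*n_c
//  4 p53 degr. in complex      -c +m         delta*n_c
//  5 Mdm2 degr. in complex     -c +p         gamma*n_c
//  6 transcription             +mm           kt/omega*n_p*(n_p-1)
//  7 mRNA decay                -mm           beta*n_mm
//  8 translation               +m            ktl*n_mm
//  9 free Mdm2 removal         -m            gamma*n_m

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

namespace {

// xoshiro256++ (public-domain algorithm), seeded through splitmix64 so any
// 64-bit seed gives a well-mixed state; one generator per run
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0 so -log() is finite
  inline double runif_pos() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
};

} // namespace

extern "C" SEXP ssa_core(SEXP ratesS, SEXP omegaS, SEXP initS, SEXP t_maxS,
                         SEXP record_dtS, SEXP seedS) {
BEGIN_RCPP
  Rcpp::NumericVector rates(ratesS), init(initS);
  const double omega = Rcpp::as<double>(omegaS);
  const double t_max = Rcpp::as<double>(t_maxS);
  const double record_dt = Rcpp::as<double>(record_dtS);
  const double seed = Rcpp::as<double>(seedS);
  const double sigma = rates["sigma"], alpha = rates["alpha"],
    delta = rates["delta"], kt = rates["k_t"], ktl = rates["k_tl"],
    beta = rates["beta"], gamma = rates["gamma"], kb = rates["k_b"],
    kf = rates["k_f"];

  double np = init[0], nmm = init[1], nm = init[2], nc = init[3];
  const double kf_w = kf / omega, kt_w = kt / omega;

  const int n_rec = static_cast<int>(std::floor(t_max / record_dt + 1e-9)) + 1;
  Rcpp::NumericMatrix out(n_rec, 5);
  Xoshiro rng(static_cast<uint64_t>(seed));

  double t = 0.0;
  int irec = 0;
  bool exhausted = false;
  // selection order puts the typically dominant channels (complex
  // formation and dissociation) first so the linear scan stays short
  double a[10];
  long long n_events = 0;
  double t_rec = 0.0;

  for (;;) {
    a[0] = kf_w * np * nm;            // complex formation
    a[1] = kb * nc;                   // complex dissociation
    a[2] = delta * nc;                // p53 degradation in complex
    a[3] = gamma * nc;                // Mdm2 degradation in complex
    a[4] = alpha * np;                // p53 removal
    a[5] = gamma * nm;                // free Mdm2 removal
    a[6] = kt_w * np * (np - 1.0);    // transcription (dimer)
    a[7] = beta * nmm;                // mRNA decay
    a[8] = ktl * nmm;                 // translation
    a[9] = sigma * omega;             // p53 production
    const double a0 = ((a[0] + a[1]) + (a[2] + a[3])) +
      ((a[4] + a[5]) + (a[6] + a[7])) + (a[8] + a[9]);

    double t_next;
    if (a0 <= 0.0) {
      t_next = t_max + record_dt;  // frozen state until the horizon
      exhausted = true;
    } else {
      t_next = t - std::log(rng.runif_pos()) / a0;
    }

    // record sample-and-hold states at grid times passed by this jump
    while (irec < n_rec && t_rec <= t_next + 1e-12) {
      out(irec, 0) = t_rec;
      out(irec, 1) = np; out(irec, 2) = nmm;
      out(irec, 3) = nm; out(irec, 4) = nc;
      ++irec;
      t_rec = irec * record_dt;
    }
    if (t_next >= t_max || irec >= n_rec) break;
    t = t_next;

    double r = rng.runif_pos() * a0;
    int j = 0;
    for (; j < 9; ++j) { if (r <= a[j]) break; r -= a[j]; }
    switch (j) {
      case 0: np -= 1; nm -= 1; nc += 1; break;
      case 1: np += 1; nm += 1; nc -= 1; break;
      case 2: nc -= 1; nm += 1; break;
      case 3: nc -= 1; np += 1; break;
      case 4: np -= 1; break;
      case 5: nm -= 1; break;
      case 6: nmm += 1; break;
      case 7: nmm -= 1; break;
      case 8: nm += 1; break;
      case 9: np += 1; break;
    }
    ++n_events;
    if ((n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::wrap(Rcpp::List::create(
    Rcpp::Named("samples") = out,
    Rcpp::Named("n_events") = static_cast<double>(n_events),
    Rcpp::Named("exhausted") = exhausted,
    Rcpp::Named("final") = Rcpp::NumericVector::create(np, nmm, nm, nc)));
END_RCPP
}
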