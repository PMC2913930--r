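/* Compiled right-hand side of the feedback-loop ODEs for deSolve.
 * Parameter vector (initparms order):
 *   0 sigma, 1 alpha, 2 delta, 3 k_t, 4 k_tl, 5 beta, 6 gamma,
 *   7 k_b, 8 k_f, 9 hill, 10 release flag (1 = gamma on the complex
 *   releases free p53, 0 = co-degradation of the whole complex)
 */
#include <R.h>
#include <math.h>

static double parms[11];

void p53_initparms(void (*odeparms)(int *, double *)) {
  int n = 11;
  odeparms(&n, parms);
}

void p53_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  const double sigma = parms[0], alpha = parms[1], delta = parms[2],
    kt = parms[3], ktl = parms[4], beta = parms[5], gamma = parms[6],
    kb = parms[7], kf = parms[8], hill = parms[9], release = parms[10];
  const double p = y[0], mm = y[1], m = y[2], c = y[3];
  const double form = kf * p * m;
  const double ph = (hill == 2.0) ? p * p : pow(p, hill);

  ydot[0] = sigma - alpha * p - form + kb * c + (release > 0.5 ? gamma * c : 0.0);
  ydot[1] = kt * ph - beta * mm;
  ydot[2] = ktl * mm - gamma * m - form + (kb + delta) * c;
  ydot[3] = form - (kb + delta + gamma) * c;
}
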