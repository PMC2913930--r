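#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP ssa_core(SEXP rates, SEXP omega, SEXP init, SEXP t_max,
              SEXP record_dt, SEXP seed);
void p53_initparms(void (*odeparms)(int *, double *));
void p53_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
  {"ssa_core", (DL_FUNC) &ssa_core, 6},
  {NULL, NULL, 0}
};

/* deSolve looks these up by name via getNativeSymbolInfo() */
static const R_CMethodDef c_entries[] = {
  {"p53_initparms", (DL_FUNC) &p53_initparms, 1},
  {"p53_derivs",    (DL_FUNC) &p53_derivs,    6},
  {NULL, NULL, 0}
};

void R_init_p53loop(DllInfo *dll) {
  R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
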