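#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* forward_sim.cpp */
SEXP C_simulate_admixture(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_focal_tracts(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

/* ode.c: deSolve entry points, looked up by name through this registry */
void admixtract_initmod(void (*odeparms)(int *, double *));
void admixtract_initforc(void (*odeforcs)(int *, double *));
void admixtract_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"C_simulate_admixture", (DL_FUNC) &C_simulate_admixture, 6},
    {"C_focal_tracts",       (DL_FUNC) &C_focal_tracts,       8},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"admixtract_initmod",  (DL_FUNC) &admixtract_initmod,  1},
    {"admixtract_initforc", (DL_FUNC) &admixtract_initforc, 1},
    {"admixtract_derivs",   (DL_FUNC) &admixtract_derivs,   6},
    {NULL, NULL, 0}
};

void R_init_admixtract(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
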