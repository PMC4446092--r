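#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_minde_setup(SEXP rates, SEXP V, SEXP A, SEXP gcyt, SEXP gmem,
                   SEXP cyl, SEXP opts);
void minde_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);
void minde_initmod(void (*odeparms)(int *, double *));

static const R_CallMethodDef call_entries[] = {
    {"C_minde_setup", (DL_FUNC) &C_minde_setup, 7},
    {NULL, NULL, 0}
};

void R_init_minde(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* minde_derivs / minde_initmod must stay findable by name for deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
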