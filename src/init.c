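#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP drum_set_rhs_data(SEXP parms);
void drum_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);
void drum_initmod(void (*odeparms)(int *, double *));

static const R_CallMethodDef call_entries[] = {
    {"drum_set_rhs_data", (DL_FUNC) &drum_set_rhs_data, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"drum_derivs", (DL_FUNC) &drum_derivs, 6},
    {"drum_initmod", (DL_FUNC) &drum_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_drumr(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
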