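#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP grn_set_model(SEXP v);
void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"C_grn_set_model", (DL_FUNC) &grn_set_model, 1},
    {NULL, NULL, 0}
};

void R_init_grnlab(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* grn_derivs is looked up by name from deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
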