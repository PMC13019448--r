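#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP c_bst_set_model(SEXP par);
void c_bst_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"c_bst_set_model", (DL_FUNC) &c_bst_set_model, 1},
    {NULL, NULL, 0}
};

/* registered as a C routine so deSolve can look it up by name */
static const R_CMethodDef c_entries[] = {
    {"c_bst_derivs", (DL_FUNC) &c_bst_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_bstkit(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
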