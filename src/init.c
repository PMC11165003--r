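#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void initmod_var(void (*odeparms)(int *, double *));
void derivs_rossler_var(int *, double *, double *, double *, double *, int *);
void derivs_lorenz_var(int *, double *, double *, double *, double *, int *);
void derivs_linear_var(int *, double *, double *, double *, double *, int *);
void event_renorm3(int *, double *, double *);
void event_renorm1(int *, double *, double *);
void derivs_net(int *, double *, double *, double *, double *, int *);
SEXP C_net_setup(SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_net_setup", (DL_FUNC) &C_net_setup, 4},
    {NULL, NULL, 0}
};

/* deSolve looks these up by name via getNativeSymbolInfo() */
static const R_CMethodDef CEntries[] = {
    {"initmod_var",        (DL_FUNC) &initmod_var,        0},
    {"derivs_rossler_var", (DL_FUNC) &derivs_rossler_var, 6},
    {"derivs_lorenz_var",  (DL_FUNC) &derivs_lorenz_var,  6},
    {"derivs_linear_var",  (DL_FUNC) &derivs_linear_var,  6},
    {"event_renorm3",      (DL_FUNC) &event_renorm3,      3},
    {"event_renorm1",      (DL_FUNC) &event_renorm1,      3},
    {"derivs_net",         (DL_FUNC) &derivs_net,         6},
    {NULL, NULL, 0}
};

void R_init_syncpath(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
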