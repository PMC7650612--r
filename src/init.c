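#include <R.h>
#include <R_ext/Rdynload.h>

void minierbb_init(void (*odeparms)(int *, double *));
void minierbb_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"minierbb_derivs", (DL_FUNC) &minierbb_derivs, 6},
    {"minierbb_init",   (DL_FUNC) &minierbb_init,   1},
    {NULL, NULL, 0}
};

void R_init_sigdyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
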