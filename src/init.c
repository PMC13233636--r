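#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void synaptode_init(void (*odeparms)(int *, double *));
void synaptode_deriv(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip);

static const R_CMethodDef cMethods[] = {
  {NULL, NULL, 0}
};

void R_init_synaptode(DllInfo *dll)
{
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE); /* deSolve looks the symbols up by name */
}
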