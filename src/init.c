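#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_calcium(SEXP, SEXP);
SEXP C_overlap(SEXP, SEXP);
SEXP C_xb_derivs(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_sarc_rhs(SEXP, SEXP, SEXP);
SEXP C_full_rhs(SEXP, SEXP, SEXP);
SEXP C_triseg(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

void ratheart_init_full(void (*)(int *, double *));
void ratheart_derivs_full(int *, double *, double *, double *, double *, int *);
void ratheart_init_sarc(void (*)(int *, double *));
void ratheart_derivs_sarc(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_calcium",   (DL_FUNC) &C_calcium,   2},
    {"C_overlap",   (DL_FUNC) &C_overlap,   2},
    {"C_xb_derivs", (DL_FUNC) &C_xb_derivs, 6},
    {"C_sarc_rhs",  (DL_FUNC) &C_sarc_rhs,  3},
    {"C_full_rhs",  (DL_FUNC) &C_full_rhs,  3},
    {"C_triseg",    (DL_FUNC) &C_triseg,    6},
    {NULL, NULL, 0}
};

/* registered so deSolve can look the compiled model up by name */
static const R_CMethodDef c_entries[] = {
    {"ratheart_init_full",   (DL_FUNC) &ratheart_init_full,   0},
    {"ratheart_derivs_full", (DL_FUNC) &ratheart_derivs_full, 0},
    {"ratheart_init_sarc",   (DL_FUNC) &ratheart_init_sarc,   0},
    {"ratheart_derivs_sarc", (DL_FUNC) &ratheart_derivs_sarc, 0},
    {NULL, NULL, 0}
};

void R_init_ratheart(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
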