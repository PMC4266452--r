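/* deSolve compiled-model glue, .Call entry points for direct right-hand-side
 * evaluation, and a fixed-step RK4 driver used as the independent reference
 * integrator in fidelity tests. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include "qtsim.h"

typedef void (*qtsim_rhs_fn)(double, const double *, const double *, double *);

static qtsim_rhs_fn rhs_table[] = {
    qtsim_rhs_tt06, qtsim_rhs_grandi, qtsim_rhs_ohara
};
static const int nstate_table[] = {
    N_STATE_TT06, N_STATE_GRANDI, N_STATE_OHARA
};

/* ---- deSolve interface (one static parameter block per model) ---- */

static double parms_tt06[QTSIM_NPAR];
static double parms_grandi[QTSIM_NPAR];
static double parms_ohara[QTSIM_NPAR];

void qtsim_init_tt06(void (*odeparms)(int *, double *))
{
    int n = QTSIM_NPAR;
    odeparms(&n, parms_tt06);
}
void qtsim_init_grandi(void (*odeparms)(int *, double *))
{
    int n = QTSIM_NPAR;
    odeparms(&n, parms_grandi);
}
void qtsim_init_ohara(void (*odeparms)(int *, double *))
{
    int n = QTSIM_NPAR;
    odeparms(&n, parms_ohara);
}

void qtsim_deriv_tt06(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    qtsim_rhs_tt06(*t, y, parms_tt06, ydot);
}
void qtsim_deriv_grandi(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    qtsim_rhs_grandi(*t, y, parms_grandi, ydot);
}
void qtsim_deriv_ohara(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    qtsim_rhs_ohara(*t, y, parms_ohara, ydot);
}

/* ---- direct RHS evaluation ---- */

SEXP qtsim_c_rhs(SEXP smodel, SEXP st, SEXP sy, SEXP sp)
{
    const int model = asInteger(smodel) - 1;
    if (model < 0 || model > 2) error("unknown model id");
    const int n = nstate_table[model];
    if (length(sy) != n) error("state vector must have length %d", n);
    if (length(sp) != QTSIM_NPAR) error("parameter vector must have length %d",
                                        QTSIM_NPAR);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    rhs_table[model](asReal(st), REAL(sy), REAL(sp), REAL(out));
    UNPROTECT(1);
    return out;
}

/* ---- fixed-step classical RK4, sampling every `sample` steps ----
 * Returns a (nsamp+1) x (1+nstate) matrix: column 1 is time, the rest the
 * state.  Entirely independent of the adaptive solver path. */

SEXP qtsim_c_rk4(SEXP smodel, SEXP sy0, SEXP sp, SEXP st0, SEXP stend,
                 SEXP sdt, SEXP ssample)
{
    const int model = asInteger(smodel) - 1;
    if (model < 0 || model > 2) error("unknown model id");
    const int n = nstate_table[model];
    if (length(sy0) != n) error("state vector must have length %d", n);
    if (length(sp) != QTSIM_NPAR) error("parameter vector must have length %d",
                                        QTSIM_NPAR);
    const double t0 = asReal(st0), tend = asReal(stend), dt = asReal(sdt);
    const int sample = asInteger(ssample);
    if (dt <= 0 || tend <= t0) error("need tend > t0 and dt > 0");
    if (sample < 1) error("'sample' must be >= 1");
    const double nsteps_d = (tend - t0) / dt;
    if (nsteps_d > 2e9) error("too many steps");
    const long nsteps = (long)(nsteps_d + 0.5);
    const long nsamp = nsteps / sample;
    qtsim_rhs_fn rhs = rhs_table[model];
    const double *p = REAL(sp);

    SEXP out = PROTECT(allocMatrix(REALSXP, (int)(nsamp + 1), n + 1));
    double *o = REAL(out);
    const long nrow = nsamp + 1;

    double y[N_STATE_OHARA], k1[N_STATE_OHARA], k2[N_STATE_OHARA],
           k3[N_STATE_OHARA], k4[N_STATE_OHARA], ytmp[N_STATE_OHARA];
    for (int i = 0; i < n; i++) y[i] = REAL(sy0)[i];

    long row = 0;
    o[row] = t0;
    for (int i = 0; i < n; i++) o[(i + 1) * nrow + row] = y[i];
    row++;

    for (long s = 0; s < nsteps; s++) {
        const double t = t0 + s * dt;
        rhs(t, y, p, k1);
        for (int i = 0; i < n; i++) ytmp[i] = y[i] + 0.5 * dt * k1[i];
        rhs(t + 0.5 * dt, ytmp, p, k2);
        for (int i = 0; i < n; i++) ytmp[i] = y[i] + 0.5 * dt * k2[i];
        rhs(t + 0.5 * dt, ytmp, p, k3);
        for (int i = 0; i < n; i++) ytmp[i] = y[i] + dt * k3[i];
        rhs(t + dt, ytmp, p, k4);
        for (int i = 0; i < n; i++)
            y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if ((s + 1) % sample == 0 && row <= nsamp) {
            o[row] = t0 + (s + 1) * dt;
            for (int i = 0; i < n; i++) o[(i + 1) * nrow + row] = y[i];
            row++;
        }
        if ((s & 0x3FFFF) == 0) R_CheckUserInterrupt();
    }
    UNPROTECT(1);
    return out;
}

/* ---- registration ---- */

static const R_CallMethodDef call_entries[] = {
    {"qtsim_c_rhs", (DL_FUNC) &qtsim_c_rhs, 4},
    {"qtsim_c_rk4", (DL_FUNC) &qtsim_c_rk4, 7},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"qtsim_init_tt06",    (DL_FUNC) &qtsim_init_tt06,    1},
    {"qtsim_init_grandi",  (DL_FUNC) &qtsim_init_grandi,  1},
    {"qtsim_init_ohara",   (DL_FUNC) &qtsim_init_ohara,   1},
    {"qtsim_deriv_tt06",   (DL_FUNC) &qtsim_deriv_tt06,   6},
    {"qtsim_deriv_grandi", (DL_FUNC) &qtsim_deriv_grandi, 6},
    {"qtsim_deriv_ohara",  (DL_FUNC) &qtsim_deriv_ohara,  6},
    {NULL, NULL, 0}
};

void R_init_qtsim(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
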