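#ifndef QTSIM_H
#define QTSIM_H

#include <math.h>

/* Shared parameter vector layout for all models.
 * p[0..5]  multiplicative scale factors on maximal conductances
 *          (quasi-steady-state conductance-block model, in [0,1] for block)
 * p[6..9]  square-pulse stimulus definition
 */
#define SC_IKR   0
#define SC_IKS   1
#define SC_INA   2
#define SC_ICAL  3
#define SC_ITO   4
#define SC_IK1   5
#define P_STIM_AMP    6   /* signed current added to dV/dt sum during pulse */
#define P_STIM_DUR    7   /* ms */
#define P_STIM_PERIOD 8   /* ms */
#define P_STIM_OFFSET 9   /* ms */
#define QTSIM_NPAR   10

#define N_STATE_TT06   19
#define N_STATE_GRANDI 39
#define N_STATE_OHARA  41

/* Square-pulse stimulus: returns the stimulus current term (with the model's
 * sign convention folded into the amplitude parameter) at time t. */
static inline double qtsim_stim(double t, const double *p)
{
    double tt = fmod(t - p[P_STIM_OFFSET], p[P_STIM_PERIOD]);
    if (tt < 0) tt += p[P_STIM_PERIOD];
    return (tt < p[P_STIM_DUR]) ? p[P_STIM_AMP] : 0.0;
}

void qtsim_rhs_tt06(double t, const double *y, const double *p, double *dy);
void qtsim_rhs_grandi(double t, const double *y, const double *p, double *dy);
void qtsim_rhs_ohara(double t, const double *y, const double *p, double *dy);

#endif
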