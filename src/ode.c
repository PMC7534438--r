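/* Six-state ancestral-configuration ODE, compiled right-hand side for
 * deSolve. States (row-vector convention, P'(t) = P(t) M(t)):
 *   1 (A-ba-ga)                 4 (a-ba-gn, A-bn-ga)
 *   2 (A-ba-gn, A-bn-ga)        5 (a-ba-gn, a-bn-ga)
 *   3 (A-ba-gn, a-bn-ga)        6 (a-ba-ga)
 * Rates: recombination r1 (alpha-beta) and r2 (beta-gamma) in Morgans,
 * coalescence lambda = 1/2Ne modulated by the selected-allele frequency
 * w(t) within the A background and 1-w(t) within the a background.
 * Frequency modes: 0 logistic in backward time, 1 constant, 2 tabulated
 * (supplied through a deSolve forcing, linearly interpolated).
 */

#include <R.h>
#include <math.h>

static double parms[6];
#define P_R1    parms[0]
#define P_R2    parms[1]
#define P_LAM   parms[2]
#define P_MODE  parms[3]
#define P_SEL   parms[4]
#define P_WCONST parms[5]

static double forc[1];
#define F_W forc[0]

void admixtract_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void admixtract_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* frequencies clamped away from {0,1}: lambda/w and lambda/(1-w) diverge
 * at the boundary which logistic trajectories never attain */
static double freq_at(double t)
{
    double w;
    if (P_MODE == 0.0) {
        double z = P_SEL * t / 2.0;
        if (z > 700.0) w = 0.0;
        else if (z < -700.0) w = 1.0;
        else w = 1.0 / (1.0 + exp(z));
    } else if (P_MODE == 1.0) {
        w = P_WCONST;
    } else {
        w = F_W;
    }
    if (w < 1e-12) w = 1e-12;
    if (w > 1.0 - 1e-12) w = 1.0 - 1e-12;
    return w;
}

void admixtract_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double w = freq_at(*t);
    const double wb = 1.0 - w;
    const double r1 = P_R1, r2 = P_R2, lam = P_LAM;
    /* cap boundary coalescence rates: above ~100/generation absorption
     * is effectively instantaneous on the generation time-scale (only
     * tabulated trajectories at numerical fixation get near the cap),
     * and uncapped rates merely destabilize the step controller */
    double cw = lam / w, cwb = lam / wb;
    if (cw > 100.0) cw = 100.0;
    if (cwb > 100.0) cwb = 100.0;

    /* ydot_j = sum_i y_i M[i][j]; M written out row by row */
    ydot[0] = -(r1 * wb + r2) * y[0] + cw * y[1] + r1 * w * y[5];
    ydot[1] = r2 * w * y[0]
        - (cw + (2.0 * r1 + r2) * wb) * y[1]
        + (r1 + r2) * w * y[2]
        + r1 * w * y[3];
    ydot[2] = r2 * wb * y[0]
        + (r1 + r2) * wb * y[1]
        - (r1 + r2 * w) * y[2]
        + r1 * w * y[4];
    ydot[3] = r1 * wb * y[1]
        - (r1 + r2 * wb) * y[3]
        + (r1 + r2) * w * y[4]
        + r2 * w * y[5];
    ydot[4] = r1 * wb * y[2]
        + (r1 + r2) * wb * y[3]
        - (cwb + (2.0 * r1 + r2) * w) * y[4]
        + r2 * wb * y[5];
    ydot[5] = r1 * wb * y[0] + cwb * y[4] - (r1 * w + r2) * y[5];
}
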