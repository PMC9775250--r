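/* Compiled right-hand side of the forced SigB partner-switching ODEs,
 * in the deSolve compiled-model convention.  Forcings (phosphatase
 * levels and the derivatives of the measured totals) are interpolated
 * by deSolve between the 1-min grid samples.
 *
 * State order: SigB_f, W2_f, V_f, W2SigB, W2V, W2V2, VP.
 * Forcing order must match run_simulation(): RsbU, RsbP, dS, dAS, dAAS.
 */
#include <R.h>

static double parms[11];
static double forcs[5];

#define k1p parms[0]
#define k1m parms[1]
#define k2p parms[2]
#define k2m parms[3]
#define k3p parms[4]
#define k4p parms[5]
#define k5p parms[6]
#define k5m parms[7]
#define k6p parms[8]
#define k6m parms[9]
#define k7p parms[10]

#define RsbU forcs[0]
#define RsbP forcs[1]
#define dS   forcs[2]
#define dAS  forcs[3]
#define dAAS forcs[4]

void sigb_initparms(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void sigb_initforcs(void (*odeforcs)(int *, double *))
{
    int n = 5;
    odeforcs(&n, forcs);
}

void sigb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double SigB_f = y[0], W2_f = y[1], V_f = y[2], W2SigB = y[3];
    double W2V = y[4], W2V2 = y[5], VP = y[6];

    double dW2SigB = k5p * W2_f * SigB_f - k5m * W2SigB
                   - k6p * W2SigB * V_f + k6m * W2V * SigB_f;
    double dW2V = k2m * W2V2 - k2p * W2V * V_f + k4p * W2V2
                + k1p * W2_f * V_f - k1m * W2V
                + k6p * W2SigB * V_f - k6m * W2V * SigB_f;
    double dW2V2 = k2p * W2V * V_f - k2m * W2V2 - k4p * W2V2;
    double dVP = k3p * W2_f * V_f + k4p * W2V2
               - k7p * VP * RsbP - k7p * VP * RsbU;

    ydot[0] = dS - dW2SigB;
    ydot[1] = 0.5 * dAS - dW2V - dW2V2 - dW2SigB;
    ydot[2] = dAAS - dW2V - 2.0 * dW2V2 - dVP;
    ydot[3] = dW2SigB;
    ydot[4] = dW2V;
    ydot[5] = dW2V2;
    ydot[6] = dVP;
}
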