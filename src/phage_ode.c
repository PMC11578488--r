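/* Strain-resolved ODE right-hand sides for the two-strain temperate-phage
 * chemostat model, in the deSolve compiled-model interface.
 *
 * State is stored in units of the carrying capacity K; the adsorption rate
 * enters pre-multiplied by K (parms[4] = a*K) so that all bilinear terms are
 * O(1).
 *
 * parms: [0] alpha_w  [1] alpha_m  [2] phi_w  [3] phi_m  [4] a*K
 *        [5] b        [6] tau      [7] B      [8] r      [9] delta
 *        [10] const_S flag (1 -> dS/dt forced to 0, onset approximation)
 */

#include <R.h>

static double parms[11];
#define NPAR 11

#define ALPHA_W parms[0]
#define ALPHA_M parms[1]
#define PHI_W   parms[2]
#define PHI_M   parms[3]
#define AK      parms[4]
#define BFUS    parms[5]
#define TAU     parms[6]
#define BURST   parms[7]
#define GROWR   parms[8]
#define DELTA   parms[9]
#define CONST_S parms[10]

void initmod_phage(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

/* Delayed-lysis model: y = (S, L_w, L_m, Y_w, Y_m, V_w, V_m) / K */
void derivs_delay(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double S = y[0], Lw = y[1], Lm = y[2], Yw = y[3], Ym = y[4],
           Vw = y[5], Vm = y[6];
    double N = S + Lw + Lm + Yw + Ym;
    double growth = GROWR * (1.0 - N);
    double foiw = AK * BFUS * Vw * S;  /* strain-specific infections */
    double foim = AK * BFUS * Vm * S;

    ydot[0] = (CONST_S > 0.5) ? 0.0
            : growth * S - (foiw + foim) - DELTA * S;
    ydot[1] = growth * Lw + PHI_W * foiw - (ALPHA_W + DELTA) * Lw;
    ydot[2] = growth * Lm + PHI_M * foim - (ALPHA_M + DELTA) * Lm;
    ydot[3] = (1.0 - PHI_W) * foiw + ALPHA_W * Lw - (TAU + DELTA) * Yw;
    ydot[4] = (1.0 - PHI_M) * foim + ALPHA_M * Lm - (TAU + DELTA) * Ym;
    ydot[5] = TAU * Yw * BURST - AK * N * Vw - DELTA * Vw;
    ydot[6] = TAU * Ym * BURST - AK * N * Vm - DELTA * Vm;
}

/* Instantaneous-lysis nested variant: y = (S, L_w, L_m, V_w, V_m) / K.
 * Lytic infections and reactivations release BURST virions immediately. */
void derivs_instant(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double S = y[0], Lw = y[1], Lm = y[2], Vw = y[3], Vm = y[4];
    double N = S + Lw + Lm;
    double growth = GROWR * (1.0 - N);
    double foiw = AK * BFUS * Vw * S;
    double foim = AK * BFUS * Vm * S;

    ydot[0] = (CONST_S > 0.5) ? 0.0
            : growth * S - (foiw + foim) - DELTA * S;
    ydot[1] = growth * Lw + PHI_W * foiw - (ALPHA_W + DELTA) * Lw;
    ydot[2] = growth * Lm + PHI_M * foim - (ALPHA_M + DELTA) * Lm;
    ydot[3] = BURST * ((1.0 - PHI_W) * foiw + ALPHA_W * Lw)
            - AK * N * Vw - DELTA * Vw;
    ydot[4] = BURST * ((1.0 - PHI_M) * foim + ALPHA_M * Lm)
            - AK * N * Vm - DELTA * Vm;
}
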