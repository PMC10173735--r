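/* Compiled right-hand sides for the CTL-melanoma ODE models, using the
 * deSolve compiled-model interface (initfunc/derivs, forcing functions for
 * the input-driven two-state model).
 *
 * Full model states (order fixed): S, G, E, I, P, PL, L, H
 * Full model parms  (order fixed): s0, se, dE, di, kgs, ksg, ki, ke,
 *                                  kA, kex, kl, kt, kp, dl, dt, dp, dpl,
 *                                  t_on (CTL transfer time; infiltration and
 *                                  expansion act only for t >= t_on)
 *
 * Forced model states: S, G;  parms: kgs, ksg, ki, ke;
 * forcings: E(t), I(t) (piecewise-linear, clamped, supplied by deSolve).
 */
#include <R.h>
#include <math.h>

static double p_full[18];
static double p_forc[4];
static double forc[2];

void ctldyn_init_full(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, p_full);
}

void ctldyn_init_forced(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, p_forc);
}

void ctldyn_forc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

static double clamp0(double x) { return x > 0.0 ? x : 0.0; }

/* volume scale below which the tumor counts as extinct; used as a smooth
 * regulariser of the per-volume terms so the vanishing-tumor limit stays
 * integrable (killing fractions -> 0 as V -> 0, no discontinuity) */
#define V_EXTINCT 1e-15

/* shared cell-cycle + killing algebra for Eqs. 3-4 style dynamics */
static void tumor_terms(double S, double G, double E, double I,
                        double kgs, double ksg, double ki, double ke,
                        double alpha, double *dS, double *dG)
{
    double V = S + G;
    double arrest = 1.0 / (1.0 + ki * I / (V + V_EXTINCT));
    double kill = alpha * ke * E;
    double fS = S / (V + V_EXTINCT);
    double fG = G / (V + V_EXTINCT);

    *dS = kgs * G * arrest - ksg * S - kill * fS;
    *dG = -kgs * G * arrest + 2.0 * ksg * S - kill * fG;
}

void ctldyn_derivs_full(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double S = clamp0(y[0]), G = clamp0(y[1]), E = clamp0(y[2]),
           I = clamp0(y[3]), P = clamp0(y[4]), PL = clamp0(y[5]),
           L = clamp0(y[6]), H = clamp0(y[7]);
    double s0 = p_full[0], se = p_full[1], dE = p_full[2], di = p_full[3],
           kgs = p_full[4], ksg = p_full[5], ki = p_full[6], ke = p_full[7],
           kA = p_full[8], kex = p_full[9], kl = p_full[10], kt = p_full[11],
           kp = p_full[12], dl = p_full[13], dt = p_full[14], dp = p_full[15],
           dpl = p_full[16], t_on = p_full[17];
    double V = S + G;
    double R = 0.0, alpha, ind, s0_eff;

    if (E > 0.0) {
        R = kl * L / E + kt * H / E + kp * (P / E) * (PL / (V + V_EXTINCT));
    }
    alpha = 1.0 / (1.0 + kex * R);

    tumor_terms(S, G, E, I, kgs, ksg, ki, ke, alpha, &ydot[0], &ydot[1]);

    s0_eff = (*t >= t_on) ? s0 : 0.0;
    ydot[2] = s0_eff * V + alpha * se * E - dE * E;
    ydot[3] = alpha * E - di * I;

    ind = E * (1.0 + kA * I / (V + V_EXTINCT));
    ydot[4] = ind - dp * P;
    ydot[5] = ind - dpl * PL;
    ydot[6] = ind - dl * L;
    ydot[7] = ind - dt * H;
}

void ctldyn_derivs_forced(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double S = clamp0(y[0]), G = clamp0(y[1]);
    double E = clamp0(forc[0]), I = clamp0(forc[1]);

    /* no exhaustion algebra in the input-driven model: alpha = 1 */
    tumor_terms(S, G, E, I, p_forc[0], p_forc[1], p_forc[2], p_forc[3],
                1.0, &ydot[0], &ydot[1]);
}
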