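/* Compiled system derivatives for the closed-loop lumped-parameter
 * circulation model (deSolve compiled-model interface).
 *
 * The parameter vector layout and the state/auxiliary-output ordering must
 * match pack_params() / c3vm_derivs_r() in R/circuit.R exactly; the R
 * implementation is the readable reference and is cross-checked against this
 * one in the test suite.
 *
 * States (15):
 *   0 V_LV, 1 V_LA, 2 P_ao_root, 3 P_SAC, 4 P_PVC, 5 P_PA,
 *   6 Q_AV, 7 Q_MV, 8 Q_PC,
 *   9/10 P_p, w (=P_m - P_im) LAD, 11/12 LCX, 13/14 RCA
 *
 * Auxiliary outputs (16):
 *   P_LV, P_LA, E_LV, q_LAD, q_LCX, q_RCA, q_out_LAD, q_out_LCX, q_out_RCA,
 *   q_ub, q_sys, q_pa, q_AR, q_MR, q_leak, q_src
 */

#include <R.h>
#include <math.h>

#define N_PARMS 59
static double parms[N_PARMS];

void c3vm_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* double-Hill elastance, normalised so the cycle maximum equals Emax */
static double hill_e(double tl, double Emax, double Emin, double m1,
                     double m2, double tau1, double tau2, double N)
{
    double g1, g2;
    if (tl <= 0.0) return Emin;
    g1 = pow(tl / tau1, m1);
    g2 = pow(tl / tau2, m2);
    return (Emax - Emin) * (g1 / (1.0 + g1)) / (1.0 + g2) / N + Emin;
}

/* smooth diode weight: ~1 only when flow is reverse AND the gradient is
 * unfavorable (blended over q_eps in flow and a 0.1 mmHg gradient window),
 * so a favorable gradient can always open the valve from q = 0 and inertial
 * forward flow is never blocked during deceleration */
static double revsig(double q, double dp, double q_eps)
{
    double xq = q / q_eps, xp = dp / 0.1, wq, wp;
    wq = (xq > 700.0) ? 0.0 : 1.0 / (1.0 + exp(xq));
    wp = (xp > 700.0) ? 0.0 : 1.0 / (1.0 + exp(xp));
    return wq * wp;
}

/* regurgitant orifice flow, smooth near zero gradient */
static double regflow(double k, double dp, double delta)
{
    if (k <= 0.0 || dp <= 0.0) return 0.0;
    return k * dp / sqrt(fabs(dp) + delta);
}

void c3vm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *p = parms;
    double T = p[0], T_EJ = p[1];
    double tc = fmod(*t, T);
    double tl_la;
    double E_LV, E_LA, P_LV, P_LA;
    double P_root = y[2], P_SAC = y[3], P_PVC = y[4], P_PA = y[5];
    double Q_AV = y[6], Q_MV = y[7], Q_PC = y[8];
    double R_bk = p[38], q_eps = p[39], delta = p[40];
    double q_AR, q_MR, q_leak, q_sys, q_ub, q_src, q_pa;
    double q_in[3], q_out[3];
    double sum_qin = 0.0;
    int j;

    if (ip[0] < 16) error("c3vm_derivs: nout must be >= 16");

    E_LV = hill_e(tc, p[2], p[3], p[4], p[5], p[6], p[7], p[9]);
    tl_la = fmod(*t - p[18], T);
    if (tl_la < 0.0) tl_la += T;
    E_LA = hill_e(tl_la, p[10], p[11], p[12], p[13], p[14], p[15], p[17]);
    P_LV = E_LV * (y[0] - p[8]);
    P_LA = E_LA * (y[1] - p[16]);

    /* valves: inertance + convective energy-loss drop + smooth reverse block */
    ydot[6] = (P_LV - P_root - p[20] * Q_AV * fabs(Q_AV)
               - R_bk * revsig(Q_AV, P_LV - P_root, q_eps) * Q_AV) / p[19];
    ydot[7] = (P_LA - P_LV - p[22] * Q_MV * fabs(Q_MV)
               - R_bk * revsig(Q_MV, P_LA - P_LV, q_eps) * Q_MV) / p[21];

    q_AR = regflow(p[23], P_root - P_LV, delta);
    q_MR = regflow(p[24], P_LV - P_LA, delta);
    q_leak = p[25] * (P_root - P_LV);

    q_sys = (P_root - P_SAC) / p[27];
    q_ub = (P_root - p[31]) / p[28];

    /* imposed pulmonary-valve inflow: half-sine of duration T_EJ, cycle
     * mean Q_MPV */
    q_src = (tc < T_EJ) ? p[37] * sin(M_PI * tc / T_EJ) : 0.0;
    ydot[4] = (q_src - Q_PC) / p[32];
    ydot[8] = (P_PVC - P_PA - p[33] * Q_PC) / p[34];
    q_pa = (P_PA - P_LA) / p[35];
    ydot[5] = (Q_PC - q_pa) / p[36];

    /* coronary branches; medial capacitor referenced to P_im */
    for (j = 0; j < 3; j++) {
        const double *cb = p + 41 + 6 * j;
        double R_p = cb[0], R_m = cb[1], R_d = cb[2];
        double C_p = cb[3], C_m = cb[4], s = cb[5];
        double P_p = y[9 + 2 * j], w = y[10 + 2 * j];
        double P_im = s * P_LV;
        double P_m = w + P_im;
        double q_m;
        q_in[j] = (P_root - P_p) / R_p;
        q_m = (P_p - P_m) / R_m;
        q_out[j] = (P_m - p[31]) / R_d;
        ydot[9 + 2 * j] = (q_in[j] - q_m) / C_p;
        ydot[10 + 2 * j] = (q_m - q_out[j]) / C_m;
        sum_qin += q_in[j];
    }

    ydot[0] = Q_MV + q_AR + q_leak - Q_AV - q_MR;
    ydot[1] = q_pa + q_MR - Q_MV;
    ydot[2] = (Q_AV - q_sys - q_ub - q_AR - q_leak - sum_qin) / p[26];
    ydot[3] = (q_sys - (P_SAC - p[31]) / p[29]) / p[30];

    yout[0] = P_LV;  yout[1] = P_LA;  yout[2] = E_LV;
    yout[3] = q_in[0]; yout[4] = q_in[1]; yout[5] = q_in[2];
    yout[6] = q_out[0]; yout[7] = q_out[1]; yout[8] = q_out[2];
    yout[9] = q_ub; yout[10] = q_sys; yout[11] = q_pa;
    yout[12] = q_AR; yout[13] = q_MR; yout[14] = q_leak; yout[15] = q_src;
}
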