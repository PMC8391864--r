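/* Compiled right-hand sides for the two IFFL circuit models, in the
 * deSolve compiled-model convention (initfunc receives the parameter
 * vector, derivs fills ydot).  Condition-dependent quantities that are
 * constant in time (Hill activations, induced plasmid pools) are folded
 * into the parameter vector on the R side; see simulate_circuit().
 */
#include <R.h>

/* ---- RNA-only model -------------------------------------------------
 * parms: 0 aXPH = alpha_X * P_X_total * H_ara
 *        1 gamma  2 omega  3 alpha_Y  4 alpha_Z  5 alpha_GFP
 *        6 dX  7 dY  8 dZ  9 dGFP  10 PY_star  11 PZ_star
 *        12 tau_T7 (transcription onset delay, min)
 *        13 constitutive-Y structural flag (0/1)
 * state: X, Y, Z, GFP
 */
static double prna[14];

void initmod_rna(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, prna);
}

void derivs_rna(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double X = y[0], Y = y[1], Z = y[2], G = y[3];
    double aXPH = (*t < prna[12]) ? 0.0 : prna[0];
    double g = prna[1], w = prna[2];
    double PYs = prna[10], PZs = prna[11];
    double yprod = prna[13] != 0.0 ? prna[3] * PYs : prna[3] * g * X * PYs;

    ydot[0] = aXPH - g * X * PYs - g * X * PZs - prna[6] * X;
    ydot[1] = yprod - prna[7] * Y - w * Y * Z;
    ydot[2] = prna[4] * g * X * PZs - prna[8] * Z - w * Y * Z;
    ydot[3] = prna[5] * Z - prna[9] * G;
}

/* ---- RNA-protein hybrid model ---------------------------------------
 * parms: 0 aXPH = alpha_X * P_X_total * H_iptg
 *        1 aYP  = alpha_Y * P_Y_total (constitutive)
 *        2 aZH  = alpha_Z * H_iptg (multiplied by free PZ here)
 *        3 gamma  4 omega  5 alpha_T  6 alpha_G
 *        7 dX  8 dY  9 dZ  10 dCY  11 dCZ  12 dT  13 dG
 *        14 katcA = k_atc * [aTc]   15 k_off   16 P_Z_total
 *        17 tau_T7
 * state: X, Y, Z, C_XY, C_XZ, T, PZ_rep, G
 */
static double phyb[18];

void initmod_hyb(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, phyb);
}

void derivs_hyb(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double X = y[0], Y = y[1], Z = y[2];
    double CXY = y[3], CXZ = y[4], T = y[5], PZr = y[6], G = y[7];
    int on = *t >= phyb[17];
    double aXPH = on ? phyb[0] : 0.0;
    double aZH = on ? phyb[2] : 0.0;
    double g = phyb[3], w = phyb[4];
    double PZ_free = phyb[16] - PZr;

    ydot[0] = aXPH - g * X * Y - g * X * Z - phyb[7] * X;
    ydot[1] = phyb[1] - g * X * Y - phyb[8] * Y;
    ydot[2] = aZH * PZ_free - g * X * Z - phyb[9] * Z;
    ydot[3] = g * X * Y - phyb[10] * CXY;
    ydot[4] = g * X * Z - phyb[11] * CXZ;
    ydot[5] = phyb[5] * CXY - w * T * PZ_free - phyb[14] * T - phyb[12] * T;
    ydot[6] = w * T * PZ_free - phyb[15] * PZr;
    ydot[7] = phyb[6] * CXZ - phyb[13] * G;
}
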