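/* Compiled right-hand side of the circulation + mitochondria model,
 * in the deSolve compiled-function interface. The parameter order must
 * match bc_param_vector() and the state order bc_state_names(); the pure-R
 * reference implementation lives in R/rhs.R and the two are tested for
 * exact agreement. */

#include <R.h>
#include <math.h>

#define N_PAR 40
#define N_FORC 3

static double parms[N_PAR];
static double forc[N_FORC];

/* parameter indices */
#define P_supps      parms[0]
#define P_uf         parms[1]
#define P_R_autc     parms[2]
#define P_tau_c      parms[3]
#define P_tau_c2     parms[4]
#define P_P_an       parms[5]
#define P_CBF_n      parms[6]
#define P_R_autp     parms[7]
#define P_k_r        parms[8]
#define P_t_r        parms[9]
#define P_tau_P      parms[10]
#define P_r_n        parms[11]
#define P_P_v        parms[12]
#define P_dPaCO2_ref parms[13]
#define P_PaCO2_n    parms[14]
#define P_H_b        parms[15]
#define P_K_O2cap    parms[16]
#define P_Km_O2      parms[17]
#define P_u          parms[18]
#define P_D_NADH     parms[19]
#define P_K_N        parms[20]
#define P_NAD_tot    parms[21]
#define P_cytox_mM   parms[22]
#define P_Dp_n       parms[23]
#define P_Dp_CV0     parms[24]
#define P_Z          parms[25]
#define P_p1         parms[26]
#define P_p2         parms[27]
#define P_p3         parms[28]
#define P_gamma1     parms[29]
#define P_gamma2     parms[30]
#define P_gamma3     parms[31]
#define P_C_buf      parms[32]
#define P_k_leak     parms[33]
#define P_r_CV       parms[34]
#define P_k1         parms[35]
#define P_k2         parms[36]
#define P_k3         parms[37]
#define P_k_prod     parms[38]
#define P_D_O2       parms[39]

/* forcings: MABP, SpO2, PaCO2 */
#define F_MABP  forc[0]
#define F_SpO2  forc[1]
#define F_PaCO2 forc[2]

void bc_initpar(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, parms);
}

void bc_initforc(void (*odeforcs)(int *, double *))
{
    int n = N_FORC;
    odeforcs(&n, forc);
}

/* states: 0 P_filt, 1 c1, 2 c2, 3 r, 4 NADH, 5 CuA_red, 6 a3_red, 7 O2, 8 Dp */
void bc_rhs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    double P_filt = y[0], c1 = y[1], c2 = y[2], r = y[3];
    double NADH = y[4], CuA_red = y[5], a3_red = y[6], O2 = y[7], Dp = y[8];

    double x = (F_PaCO2 - P_PaCO2_n) / P_dPaCO2_ref;
    ydot[0] = (F_MABP - P_filt) / P_tau_P;
    ydot[1] = (x - c1) / P_tau_c;
    ydot[2] = (x - c2) / P_tau_c2;

    double r_inf = P_r_n * (1.0 + P_k_r *
        tanh(P_R_autc * c1 - P_R_autp * (P_filt / P_P_an - 1.0)));
    ydot[3] = (r_inf - r) / P_t_r;

    double rr = r / P_r_n;
    double CBF = P_CBF_n * rr * rr * rr * rr * (F_MABP - P_P_v) / (P_P_an - P_P_v);

    double u_eff = P_u * (1.0 + P_uf * c2);
    if (u_eff < 0.0) u_eff = 0.0;
    double NADf = 1.0 - NADH;
    double supply = P_k_prod * pow(P_u, 2.0 * P_D_NADH) * (1.0 - P_supps * c2);
    if (supply < 0.0) supply = 0.0;
    double J_prod = supply * NADf / (NADf + P_K_N);

    double dD = (Dp - P_Dp_n) / P_Z;
    double e1 = exp(-P_gamma1 * dD);
    double e2 = exp(-P_gamma2 * dD);
    double e3 = exp(-P_gamma3 * dD);
    double O2c = O2 > 0.0 ? O2 : 0.0;
    double f1 = P_k1 * (1.0 - CuA_red) * NADH * e1;
    double f2 = P_k2 * CuA_red * (1.0 - a3_red) * e2;
    double f3 = P_k3 * a3_red * (O2c / (O2c + P_Km_O2)) * e3;

    double CMRO2 = f3 / 4.0;
    double SvO2 = F_SpO2 - CMRO2 / (CBF * P_H_b);
    if (SvO2 < 0.0) SvO2 = 0.0;
    if (SvO2 > F_SpO2) SvO2 = F_SpO2;
    double O2cap = P_K_O2cap * (F_SpO2 + SvO2) / 2.0;
    double J_O2 = P_D_O2 * (O2cap - O2);

    double L_CV = 0.0;
    if (Dp > P_Dp_CV0)
        L_CV = P_r_CV * u_eff * (exp((Dp - P_Dp_CV0) / P_Z) - 1.0);
    double L_leak = P_k_leak * Dp;

    ydot[4] = (J_prod - f1 / 2.0) / P_NAD_tot;
    ydot[5] = (f1 - f2) / P_cytox_mM;
    ydot[6] = (f2 - f3) / P_cytox_mM;
    ydot[7] = J_O2 - f3 / 4.0;
    ydot[8] = (P_p1 * f1 + P_p2 * f2 + P_p3 * f3 - L_CV - L_leak) / P_C_buf;
}
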