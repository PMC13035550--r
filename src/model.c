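/* Multiscale cardiopulmonary model core.
 *
 * State layout of the full closed-loop model (46 states):
 *   [ 0..32]  crossbridge kinetics, 11 per wall (LV, SEP, RV):
 *             p1_0,p1_1,p1_2, p2_0,p2_1,p2_2, p3_0,p3_1,p3_2, N_np, U_SR
 *   [33..35]  contractile sarcomere length L_s per wall (um)
 *   [36..39]  TriSeg geometric unknowns x_m_LV, x_m_SEP, x_m_RV, y_m (cm);
 *             algebraic rows (zero rows of the mass matrix): the "derivative"
 *             slots carry the two cap-volume residuals and the axial/radial
 *             midwall tension balances.
 *   [40..45]  compartment volumes V_LV, V_RV, V_SA, V_SV, V_PA, V_PV (mL)
 *
 * Units: time s, length cm (sarcomere um), volume mL, stress kPa,
 * pressure mmHg at the circulation level (kPa inside wall mechanics).
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* packed parameter vector indices (must match R's pack_sim_params()) */
#define IP_T        0
#define IP_CADIA    1
#define IP_CAAMP    2
#define IP_KTS      3
#define IP_KTR      4
#define IP_NH       5
#define IP_KON      6
#define IP_KOFF     7   /* 7,8,9: LV,SEP,RV */
#define IP_FA       10
#define IP_GD       11
#define IP_F12      12
#define IP_G21      13
#define IP_F23      14
#define IP_F3M      15
#define IP_KS1      16  /* 16..18 */
#define IP_KS2      19  /* 19..21 */
#define IP_DR       22
#define IP_SIGB     23
#define IP_KSR      24
#define IP_KMSR     25
#define IP_KPAS     26  /* 26..28 */
#define IP_GAMMA    29
#define IP_LSC0     30
#define IP_ETA      31
#define IP_KSE      32
#define IP_LSREF    33
#define IP_AMREF    34  /* 34..36 */
#define IP_VW       37  /* 37..39 */
#define IP_CSA      40
#define IP_CSV      41
#define IP_CPA      42
#define IP_CPV      43
#define IP_RSA      44
#define IP_RPA      45
#define IP_RM       46
#define IP_RA       47
#define IP_RT       48
#define IP_RP       49
#define IP_VUN      50  /* 50..53: SA,SV,PA,PV */
#define IP_OVLA0    54
#define IP_OVLP1    55
#define IP_OVLP2    56
#define IP_OVLD0    57
#define NPAR_FULL   58
/* sarcomere-only extras */
#define IP_CAMODE   58  /* 0 = constant Ca, 1 = transient */
#define IP_CAVAL    59
#define IP_LSW      60  /* fixed wall-level sarcomere length (isometric) */
#define IP_WALL     61  /* 0 LV, 1 SEP, 2 RV */
#define NPAR_SARC   62

#define N_FULL      46
#define N_SARC      12
#define NOUT_FULL   17

#define KPA_PER_MMHG 0.133322

static double parms_full[NPAR_FULL];
static double parms_sarc[NPAR_SARC];

/* ------------------------------------------------------------------ */
/* calcium transient: raised-cosine rise over T_S, fall over T_R       */
static double ca_transient_c(double t, const double *p)
{
    double T  = p[IP_T];
    double TS = p[IP_KTS] * T;
    double TR = p[IP_KTR] * T;
    double tm = fmod(t, T);
    if (tm < 0) tm += T;
    if (tm < TS)
        return p[IP_CADIA] + p[IP_CAAMP] * 0.5 * (1.0 - cos(M_PI * tm / TS));
    if (tm <= TS + TR)
        return p[IP_CADIA] + p[IP_CAAMP] * 0.5 * (1.0 + cos(M_PI * (tm - TS) / TR));
    return p[IP_CADIA];
}

/* thick-filament overlap: piecewise-linear tent with unit plateau */
static double overlap_c(double L, const double *p)
{
    double a = p[IP_OVLA0], b = p[IP_OVLP1], c = p[IP_OVLP2], d = p[IP_OVLD0];
    double up = (L - a) / (b - a);
    double dn = (d - L) / (d - c);
    double ov = up < dn ? up : dn;
    if (ov > 1.0) ov = 1.0;
    if (ov < 0.0) ov = 0.0;
    return ov;
}

/* crossbridge moment derivatives for one wall.
 * w: 11 states; v: strain (half-sarcomere) sliding velocity um/s.
 * Attachment inserts heads at zero strain, so only 0th moments gain
 * source terms from attachment; sliding advects the distributions
 * (d p^k/dt gains k*v*p^{k-1}). Constant transition rates keep the
 * moment hierarchy exactly closed. Detachment from the post-ratchet
 * state is strain-energy assisted (Boltzmann factor on the working
 * stroke), which saturates the stiffness -> force map.               */
static void xb_derivs_c(const double *w, double Ca, double ov, double v,
                        int wall, const double *p, double *dw)
{
    double p10 = w[0], p11 = w[1], p12 = w[2];
    double p20 = w[3], p21 = w[4], p22 = w[5];
    double p30 = w[6], p31 = w[7], p32 = w[8];
    double Nnp = w[9], Usr = w[10];

    double U = 1.0 - p10 - p20 - p30 - Usr;   /* all unattached, non-SR  */
    double P = U - Nnp;                       /* permissible, unattached */
    if (P < 0.0) P = 0.0;

    double koff = p[IP_KOFF + wall];
    double ks2  = p[IP_KS2 + wall];
    double gd   = p[IP_GD];
    double f12  = p[IP_F12];
    double g21  = p[IP_G21];
    double f23  = p[IP_F23];

    /* exit from the post-ratchet state is assisted by the stored stroke
       energy: faster when shortening drives the mean strain negative,
       saturating the stiffness -> force relation at isometric */
    double s3   = (p30 > 1e-12) ? p31 / p30 : 0.0;
    double e3   = p[IP_DR] - s3;            /* residual stroke extension */
    if (e3 < 0.0) e3 = 0.0;                 /* lengthening cannot slow exit
                                               below the base rate */
    double f3   = p[IP_F3M] * exp(ks2 * e3 / p[IP_SIGB]);

    double kact = (Ca > 0.0) ? p[IP_KON] * pow(Ca, p[IP_NH]) : 0.0;
    double att  = p[IP_FA] * ov * P;

    dw[0] = att - (gd + f12) * p10 + g21 * p20;
    dw[1] = v * p10 - (gd + f12) * p11 + g21 * p21;
    dw[2] = 2.0 * v * p11 - (gd + f12) * p12 + g21 * p22;
    dw[3] = f12 * p10 - (g21 + f23) * p20;
    dw[4] = f12 * p11 + v * p20 - (g21 + f23) * p21;
    dw[5] = f12 * p12 + 2.0 * v * p21 - (g21 + f23) * p22;
    dw[6] = f23 * p20 - f3 * p30;
    dw[7] = f23 * p21 + v * p30 - f3 * p31;
    dw[8] = f23 * p22 + 2.0 * v * p31 - f3 * p32;
    dw[9]  = -kact * Nnp + koff * P;
    dw[10] = p[IP_KSR] * P - p[IP_KMSR] * Usr;
}

static double active_stress_c(const double *w, double ov, int wall,
                              const double *p)
{
    double ks1 = p[IP_KS1 + wall];
    double ks2 = p[IP_KS2 + wall];
    return ov * (ks1 * (w[4] + w[7]) + ks2 * p[IP_DR] * w[6]);
}

static double passive_stress_c(double L, int wall, const double *p)
{
    double e = L - p[IP_LSC0];
    if (e <= 0.0) return 0.0;
    return p[IP_KPAS + wall] * pow(e, p[IP_GAMMA]);
}

/* ------------------------------------------------------------------ */
/* TriSeg spherical-cap geometry.
 * Each wall is a spherical cap through a common circular junction of
 * radius y; cap height x is signed positive toward the RV.            */

static double cap_volume(double x, double y)
{
    return M_PI / 6.0 * x * (x * x + 3.0 * y * y);
}

typedef struct {
    double Am[3], Cm[3], z[3], Lsw[3], Tm[3], Tx[3], Ty[3];
    double res[4];
    double P_LV, P_RV;  /* mmHg */
} triseg_t;

static void triseg_eval(const double x[3], double y,
                        const double Vw[3], const double Amref[3],
                        double Lsref, const double sig[3],
                        double VLV, double VRV, triseg_t *o)
{
    for (int w = 0; w < 3; w++) {
        double q  = x[w] * x[w] + y * y;
        double Am = M_PI * q;
        double Cm = 2.0 * x[w] / q;
        double z  = 3.0 * Cm * Vw[w] / (2.0 * Am);
        double ef = 0.5 * log(Am / Amref[w]) - z * z / 12.0
                    - 0.019 * z * z * z * z;
        double Tm = Vw[w] * sig[w] * (1.0 + z * z / 3.0
                    + z * z * z * z / 5.0) / Am;
        o->Am[w] = Am; o->Cm[w] = Cm; o->z[w] = z;
        o->Lsw[w] = Lsref * exp(ef);
        o->Tm[w] = Tm;
        o->Tx[w] = Tm * 2.0 * x[w] * y / q;   /* axial component  */
        o->Ty[w] = Tm * (y * y - x[w] * x[w]) / q; /* radial component */
    }
    o->res[0] = cap_volume(x[1], y) - cap_volume(x[0], y)
                - (VLV + 0.5 * Vw[0] + 0.5 * Vw[1]);
    o->res[1] = cap_volume(x[2], y) - cap_volume(x[1], y)
                - (VRV + 0.5 * Vw[2] + 0.5 * Vw[1]);
    o->res[2] = o->Tx[0] + o->Tx[1] + o->Tx[2];
    o->res[3] = o->Ty[0] + o->Ty[1] + o->Ty[2];
    o->P_LV = -2.0 * o->Tx[0] / y / KPA_PER_MMHG;
    o->P_RV =  2.0 * o->Tx[2] / y / KPA_PER_MMHG;
}

/* ------------------------------------------------------------------ */
/* full model RHS */
static void full_rhs(double t, const double *y, double *ydot, double *yout,
                     const double *p)
{
    const double *Vw    = p + IP_VW;
    const double *Amref = p + IP_AMREF;
    double x[3] = { y[36], y[37], y[38] };
    double ym   = y[39];
    double VLV = y[40], VRV = y[41];
    double sig[3], sigXB[3], sigpas[3], dLs[3];
    triseg_t g;

    double Ca = ca_transient_c(t, p);

    /* series-element (= total transmitted) wall stress, kPa */
    /* first need L_s_wall from geometry; evaluate with unit stresses to
       get Lsw, then recompute tensions with the real stresses          */
    double unit[3] = { 0.0, 0.0, 0.0 };
    triseg_eval(x, ym, Vw, Amref, p[IP_LSREF], unit, VLV, VRV, &g);
    for (int w = 0; w < 3; w++) {
        double Ls = y[33 + w];
        sig[w] = p[IP_KSE] * (g.Lsw[w] - Ls);
    }
    triseg_eval(x, ym, Vw, Amref, p[IP_LSREF], sig, VLV, VRV, &g);

    for (int w = 0; w < 3; w++) {
        double Ls = y[33 + w];
        double ov = overlap_c(Ls, p);
        sigXB[w]  = active_stress_c(y + 11 * w, ov, w, p);
        sigpas[w] = passive_stress_c(Ls, w, p);
        dLs[w] = (sig[w] - sigXB[w] - sigpas[w]) / p[IP_ETA];
        xb_derivs_c(y + 11 * w, Ca, ov, 0.5 * dLs[w], w, p, ydot + 11 * w);
        ydot[33 + w] = dLs[w];
    }

    /* TriSeg algebraic rows */
    ydot[36] = g.res[0];
    ydot[37] = g.res[1];
    ydot[38] = g.res[2];
    ydot[39] = g.res[3];

    /* circulation (pressures mmHg, flows mL/s) */
    double PLV = g.P_LV, PRV = g.P_RV;
    double PSA = (y[42] - p[IP_VUN + 0]) / p[IP_CSA];
    double PSV = (y[43] - p[IP_VUN + 1]) / p[IP_CSV];
    double PPA = (y[44] - p[IP_VUN + 2]) / p[IP_CPA];
    double PPV = (y[45] - p[IP_VUN + 3]) / p[IP_CPV];

    double Qm = PPV > PLV ? (PPV - PLV) / p[IP_RM] : 0.0;
    double Qa = PLV > PSA ? (PLV - PSA) / p[IP_RA] : 0.0;
    double Qt = PSV > PRV ? (PSV - PRV) / p[IP_RT] : 0.0;
    double Qp = PRV > PPA ? (PRV - PPA) / p[IP_RP] : 0.0;
    double Qsa = (PSA - PSV) / p[IP_RSA];
    double Qpa = (PPA - PPV) / p[IP_RPA];

    ydot[40] = Qm - Qa;    /* V_LV */
    ydot[41] = Qt - Qp;    /* V_RV */
    ydot[42] = Qa - Qsa;   /* V_SA */
    ydot[43] = Qsa - Qt;   /* V_SV */
    ydot[44] = Qp - Qpa;   /* V_PA */
    ydot[45] = Qpa - Qm;   /* V_PV */

    if (yout) {
        yout[0] = PLV;  yout[1] = PRV;
        yout[2] = PSA;  yout[3] = PSV;
        yout[4] = PPA;  yout[5] = PPV;
        yout[6] = g.Cm[1];
        yout[7] = sigXB[0]; yout[8] = sigXB[1]; yout[9] = sigXB[2];
        yout[10] = Qm;  yout[11] = Qa; yout[12] = Qt; yout[13] = Qp;
        yout[14] = Qsa; yout[15] = Qpa;
        yout[16] = Ca;
    }
}

/* isolated sarcomere RHS (isometric wall, 11 kinetic states + L_s) */
static void sarc_rhs(double t, const double *y, double *ydot, double *yout,
                     const double *p)
{
    int wall = (int) p[IP_WALL];
    double Ca = (p[IP_CAMODE] > 0.5) ? ca_transient_c(t, p) : p[IP_CAVAL];
    double Ls = y[11];
    double ov = overlap_c(Ls, p);
    double sXB  = active_stress_c(y, ov, wall, p);
    double spas = passive_stress_c(Ls, wall, p);
    double sSE  = p[IP_KSE] * (p[IP_LSW] - Ls);
    double dLs  = (sSE - sXB - spas) / p[IP_ETA];
    xb_derivs_c(y, Ca, ov, 0.5 * dLs, wall, p, ydot);
    ydot[11] = dLs;
    if (yout) { yout[0] = sXB; yout[1] = Ca; }
}

/* ------------------------------------------------------------------ */
/* deSolve compiled-model interface */

void ratheart_init_full(void (*odeparms)(int *, double *))
{
    int n = NPAR_FULL;
    odeparms(&n, parms_full);
}

void ratheart_derivs_full(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    full_rhs(*t, y, ydot, (ip[0] >= NOUT_FULL) ? yout : NULL, parms_full);
}

void ratheart_init_sarc(void (*odeparms)(int *, double *))
{
    int n = NPAR_SARC;
    odeparms(&n, parms_sarc);
}

void ratheart_derivs_sarc(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    sarc_rhs(*t, y, ydot, (ip[0] >= 2) ? yout : NULL, parms_sarc);
}

/* ------------------------------------------------------------------ */
/* .Call helpers for unit-level operations and tests */

SEXP C_calcium(SEXP t, SEXP pars)
{
    int n = LENGTH(t);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (int i = 0; i < n; i++)
        REAL(out)[i] = ca_transient_c(REAL(t)[i], REAL(pars));
    UNPROTECT(1);
    return out;
}

SEXP C_overlap(SEXP L, SEXP pars)
{
    int n = LENGTH(L);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (int i = 0; i < n; i++)
        REAL(out)[i] = overlap_c(REAL(L)[i], REAL(pars));
    UNPROTECT(1);
    return out;
}

SEXP C_xb_derivs(SEXP w, SEXP Ca, SEXP ov, SEXP v, SEXP wall, SEXP pars)
{
    SEXP out = PROTECT(allocVector(REALSXP, 11));
    xb_derivs_c(REAL(w), asReal(Ca), asReal(ov), asReal(v),
                asInteger(wall), REAL(pars), REAL(out));
    UNPROTECT(1);
    return out;
}

SEXP C_sarc_rhs(SEXP t, SEXP y, SEXP pars)
{
    SEXP out = PROTECT(allocVector(REALSXP, N_SARC + 2));
    double yout[2];
    sarc_rhs(asReal(t), REAL(y), REAL(out), yout, REAL(pars));
    REAL(out)[N_SARC]     = yout[0];
    REAL(out)[N_SARC + 1] = yout[1];
    UNPROTECT(1);
    return out;
}

SEXP C_full_rhs(SEXP t, SEXP y, SEXP pars)
{
    SEXP out = PROTECT(allocVector(REALSXP, N_FULL + NOUT_FULL));
    full_rhs(asReal(t), REAL(y), REAL(out), REAL(out) + N_FULL, REAL(pars));
    UNPROTECT(1);
    return out;
}

/* geometry evaluation: residuals + derived quantities.
 * geom = (x_LV, x_SEP, x_RV, y); vols = (V_LV, V_RV); sig = 3 wall
 * stresses kPa; vw, amref = 3 each; lsref scalar.
 * returns c(res[4], Am[3], Cm[3], Lsw[3], Tx[3], Ty[3], P_LV, P_RV)  */
SEXP C_triseg(SEXP geom, SEXP vols, SEXP sig, SEXP vw, SEXP amref, SEXP lsref)
{
    triseg_t g;
    double x[3] = { REAL(geom)[0], REAL(geom)[1], REAL(geom)[2] };
    triseg_eval(x, REAL(geom)[3], REAL(vw), REAL(amref), asReal(lsref),
                REAL(sig), REAL(vols)[0], REAL(vols)[1], &g);
    SEXP out = PROTECT(allocVector(REALSXP, 21));
    double *o = REAL(out);
    for (int i = 0; i < 4; i++) o[i] = g.res[i];
    for (int w = 0; w < 3; w++) {
        o[4 + w] = g.Am[w];  o[7 + w]  = g.Cm[w];
        o[10 + w] = g.Lsw[w]; o[13 + w] = g.Tx[w]; o[16 + w] = g.Ty[w];
    }
    o[19] = g.P_LV; o[20] = g.P_RV;
    UNPROTECT(1);
    return out;
}
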