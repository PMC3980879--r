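/* Compiled right-hand side of the IL-2 cohort ODE model, for deSolve.
 *
 * State vector (length n_clones + 1 + 4 * n_cells):
 *   y[0 .. K-1]   free pMHC molecules per clone, in the scaled cohort volume
 *   y[K]          extracellular IL-2 concentration (molar)
 *   then per cell i: IL-2Ralpha, IL-2Rbeta/gamma, bound IL-2/IL-2R complex,
 *   activated Boost (all molecule counts).
 *
 * Parameter vector layout (packed by pack_parms() in R/simulate.R):
 *   [0] n_clones K, [1] n_cells M,
 *   then K blocks of N_SCALAR per-clone scalars (order below),
 *   then K per-clone cohort scales S_k = N_Tcell_k / n_sim_cells_k,
 *   then M per-cell 0-based clone indices,
 *   then M per-cell activation times (h).
 * Cross-talk / boost toggles are encoded by zeroing sigma_TCR_inh and the
 * Boost rate constants in the packed block.
 *
 * Extra outputs (yout): per-cell pSTAT5 fraction, secretion gate, engaged TCR.
 */
#include <R.h>
#include <math.h>

#define N_SCALAR 23
#define MAX_CLONES 8
#define PARMS_LEN 40000

static double parms[PARMS_LEN];

void il2_initmod(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, parms);
}

/* equilibrium complex count for X + Y <-> XY with equilibrium constant K;
 * numerically stable form of the mass-action quadratic root */
static double eq_complex(double x, double y, double K)
{
    double b, d;
    if (x <= 0.0 || y <= 0.0) return 0.0;
    b = x + y + K;
    d = b * b - 4.0 * x * y;
    d = d > 0.0 ? sqrt(d) : 0.0;
    return 2.0 * x * y / (b + d);
}

/* indices into a per-clone scalar block */
enum {
    I_K_TCR, I_K_PRE, I_SIG_TCR, I_K_P5, I_K_AG, I_TAU, I_RA_TCR, I_K_DEG,
    I_RA_P5, I_RB0, I_RBMAX, I_K_BIND, I_K_ENDO, I_K_BAS, I_SIG_P5, I_NBTOT,
    I_K_TB, I_K_BB, I_K_BIL2, I_NTCR0, I_V, I_NA, I_JAK
};

void il2_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int K = (int) parms[0];
    const int M = (int) parms[1];
    const double *blk0  = parms + 2;
    const double *S     = parms + 2 + K * N_SCALAR;
    const double *clone = S + K;
    const double *tact  = clone + M;
    const double VNA    = blk0[I_V] * blk0[I_NA];   /* shared culture volume */

    const double c_il2 = y[K] > 0.0 ? y[K] : 0.0;
    double engaged_cl[MAX_CLONES], dpmhc[MAX_CLONES];
    int nact[MAX_CLONES];
    double dc = 0.0;
    int i, k;

    if (ip[0] < 3 * M) Rf_error("il2_derivs: nout too small");

    for (k = 0; k < K; k++) nact[k] = 0;
    for (i = 0; i < M; i++)
        if (*t >= tact[i]) nact[(int) clone[i]]++;

    /* engaged TCR is shared by all active cells of a clone: each active cell
     * sees an equal share of its clone's free cognate-antigen pool */
    for (k = 0; k < K; k++) {
        const double *b = blk0 + k * N_SCALAR;
        double pm = y[k] > 0.0 ? y[k] : 0.0;
        engaged_cl[k] = nact[k] > 0 ?
            eq_complex(b[I_NTCR0], pm / nact[k], b[I_K_TCR]) : 0.0;
        dpmhc[k] = 0.0;
    }

    for (i = 0; i < M; i++) {
        int    ci   = (int) clone[i];
        const double *b = blk0 + ci * N_SCALAR;
        double eng  = (*t >= tact[i]) ? engaged_cl[ci] : 0.0;
        double Ra   = y[K + 1 + 4 * i],     dRa;
        double Rb   = y[K + 1 + 4 * i + 1], dRb;
        double cplx = y[K + 1 + 4 * i + 2], dcplx;
        double bst  = y[K + 1 + 4 * i + 3], dbst;
        double act  = eng >= b[I_TAU] ? 1.0 : 0.0;
        double preR, p5, bind, fb, gate, secr;

        if (Ra < 0.0) Ra = 0.0;
        if (Rb < 0.0) Rb = 0.0;
        if (cplx < 0.0) cplx = 0.0;
        if (bst < 0.0) bst = 0.0;
        if (bst > b[I_NBTOT]) bst = b[I_NBTOT];

        preR = eq_complex(Ra, Rb, b[I_K_PRE]);
        p5 = b[I_JAK] != 0.0 ? 0.0 :
            cplx / (b[I_K_P5] + cplx) / (1.0 + b[I_SIG_TCR] * eng);

        dRa = b[I_K_DEG] * (b[I_RA_TCR] * act + b[I_RA_P5] * p5 - Ra);
        dRb = b[I_K_DEG] * (b[I_RB0] + (b[I_RBMAX] - b[I_RB0]) * act - Rb);

        bind  = b[I_K_BIND] * c_il2 * (preR - cplx);
        dcplx = bind - b[I_K_ENDO] * cplx;

        /* TCR seeding (molecules/h per engaged TCR) plus autocatalysis (1/h),
         * both acting on the remaining inactive fraction */
        fb   = bst / b[I_NBTOT];
        dbst = (b[I_K_TB] * eng + b[I_K_BB] * bst) * (1.0 - fb);

        gate = eng / (1.0 + b[I_SIG_P5] * p5) >= b[I_TAU] ? 1.0 : 0.0;
        secr = (b[I_K_BAS] + b[I_K_BIL2] * fb) * gate;

        dpmhc[ci] -= b[I_K_AG] * eng;
        dc += S[ci] * (secr - bind) / VNA;

        ydot[K + 1 + 4 * i]     = dRa;
        ydot[K + 1 + 4 * i + 1] = dRb;
        ydot[K + 1 + 4 * i + 2] = dcplx;
        ydot[K + 1 + 4 * i + 3] = dbst;

        yout[i]         = p5;
        yout[M + i]     = gate;
        yout[2 * M + i] = eng;
    }

    for (k = 0; k < K; k++)
        ydot[k] = (y[k] > 0.0 || dpmhc[k] > 0.0) ? dpmhc[k] : 0.0;
    ydot[K] = dc;
}
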