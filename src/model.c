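/* Compiled right-hand side of the mitochondrial H2O2 reaction network
 * for use with deSolve's compiled-model interface.
 *
 * Species order and reaction order must match R/reactions.R exactly;
 * the test suite asserts bit-level agreement between this routine and
 * the R reference implementation on random states.
 *
 * Parameter vector (length 32):
 *   parms[0..29]  k1..k30  (k5 is the Michaelis constant of the NADPH
 *                 regeneration step, k20 its maximal rate; k28 = kDAAO,
 *                 k30 = kefflux)
 *   parms[30]     efflux mode: 0 = zeroth order (throttled below eps),
 *                 1 = first order in H2O2
 *   parms[31]     eps, the throttle scale of the zeroth-order efflux (uM)
 */

static double parms[32];

#define K(i) parms[(i) - 1]
#define EFFLUX_MODE parms[30]
#define EFFLUX_EPS  parms[31]

void mitoredox_initmod(void (*odeparms)(int *, double *))
{
    int n = 32;
    odeparms(&n, parms);
}

/* species indices (0-based) */
enum {
    iH2O2 = 0,
    iPrx3_SH, iPrx3_SOH, iPrx3_SS, iPrx3_SOOH,
    iPrx5_SH, iPrx5_SOH, iPrx5_SS,
    iGpx1_red, iGpx1_ox, iGpx1_SSG,
    iGpx4_red, iGpx4_ox, iGpx4_SSG,
    iTrx2_SH, iTrx2_SS,
    iGSH, iGSSG,
    iNADPH, iNADPp,
    iPr_SH, iPr_SOH, iPr_SSG,
    iPr_SH2, iPr_SS,
    iGrx2_SH, iGrx2_SSG,
    iSrx
};

void mitoredox_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double v[30];
    double throttle;

    v[0]  = K(1);                                  /* H2O2 source (OxPhos) */
    v[1]  = K(2)  * y[iGpx1_red]  * y[iH2O2];
    v[2]  = K(3)  * y[iGpx1_ox]   * y[iGSH];
    v[3]  = K(4)  * y[iGpx1_SSG]  * y[iGSH];
    v[4]  = K(20) * y[iNADPp] / (K(5) + y[iNADPp]); /* NADPH regeneration */
    v[5]  = K(6)  * y[iPrx3_SH]   * y[iH2O2];
    v[6]  = K(7)  * y[iPrx3_SOH]  * y[iH2O2];      /* hyperoxidation */
    v[7]  = K(8)  * y[iPrx3_SOOH] * y[iSrx];       /* Srx repair */
    v[8]  = K(9)  * y[iPrx3_SOH];                  /* resolution */
    v[9]  = K(10) * y[iPrx3_SS]   * y[iTrx2_SH];
    v[10] = K(11) * y[iGSH];                       /* GSH autoxidation */
    v[11] = K(12) * y[iPr_SH]     * y[iH2O2];
    v[12] = K(13) * y[iPr_SOH]    * y[iGSH];
    v[13] = K(14) * y[iGrx2_SH]   * y[iPr_SSG];
    v[14] = K(15) * y[iGrx2_SSG]  * y[iGSH];
    v[15] = K(16) * y[iPr_SH2]    * y[iH2O2];
    v[16] = K(17) * y[iPr_SS]     * y[iTrx2_SH];
    v[17] = K(18) * y[iGSSG]      * y[iNADPH];
    v[18] = K(19) * y[iTrx2_SS]   * y[iNADPH];
    v[19] = K(21);                                 /* GSH import */
    v[20] = K(22) * y[iGSH];                       /* GSH efflux */
    v[21] = K(23) * y[iPrx5_SH]   * y[iH2O2];
    v[22] = K(24) * y[iPrx5_SOH];
    v[23] = K(25) * y[iPrx5_SS]   * y[iTrx2_SH];
    v[24] = K(26) * y[iGpx4_red]  * y[iH2O2];
    v[25] = K(27) * y[iGpx4_ox]   * y[iGSH];
    v[26] = K(4)  * y[iGpx4_SSG]  * y[iGSH];
    v[27] = K(28);                                 /* H2O2 source (DAAO) */
    v[28] = K(29);                                 /* Srx import */
    if (EFFLUX_MODE < 0.5) {
        throttle = y[iH2O2] / EFFLUX_EPS;
        if (throttle > 1.0) throttle = 1.0;
        v[29] = K(30) * throttle;                  /* zeroth-order efflux */
    } else {
        v[29] = K(30) * y[iH2O2];                  /* first-order efflux */
    }

    ydot[iH2O2]      = v[0] + v[27] - v[29]
                       - v[1] - v[5] - v[6] - v[11] - v[15] - v[21] - v[24];
    ydot[iPrx3_SH]   = v[9] - v[5];
    ydot[iPrx3_SOH]  = v[5] + v[7] - v[6] - v[8];
    ydot[iPrx3_SS]   = v[8] - v[9];
    ydot[iPrx3_SOOH] = v[6] - v[7];
    ydot[iPrx5_SH]   = v[23] - v[21];
    ydot[iPrx5_SOH]  = v[21] - v[22];
    ydot[iPrx5_SS]   = v[22] - v[23];
    ydot[iGpx1_red]  = v[3] - v[1];
    ydot[iGpx1_ox]   = v[1] - v[2];
    ydot[iGpx1_SSG]  = v[2] - v[3];
    ydot[iGpx4_red]  = v[26] - v[24];
    ydot[iGpx4_ox]   = v[24] - v[25];
    ydot[iGpx4_SSG]  = v[25] - v[26];
    ydot[iTrx2_SH]   = v[18] - v[9] - v[16] - v[23];
    ydot[iTrx2_SS]   = v[9] + v[16] + v[23] - v[18];
    ydot[iGSH]       = v[19] + 2.0 * v[17]
                       - v[2] - v[3] - v[10] - v[12] - v[14] - v[20]
                       - v[25] - v[26];
    ydot[iGSSG]      = 0.5 * v[10] + v[3] + v[14] + v[26] - v[17];
    ydot[iNADPH]     = v[4] - v[17] - v[18];
    ydot[iNADPp]     = v[17] + v[18] - v[4];
    ydot[iPr_SH]     = v[13] - v[11];
    ydot[iPr_SOH]    = v[11] - v[12];
    ydot[iPr_SSG]    = v[12] - v[13];
    ydot[iPr_SH2]    = v[16] - v[15];
    ydot[iPr_SS]     = v[15] - v[16];
    ydot[iGrx2_SH]   = v[14] - v[13];
    ydot[iGrx2_SSG]  = v[13] - v[14];
    ydot[iSrx]       = v[28] - v[7];
}
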