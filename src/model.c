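/* Combined ErbB signaling + drug pharmacology + mouse PK + tumor growth ODE
 * right-hand side, in the compiled-model form understood by deSolve
 * (initfunc = "initmod", derivs = "derivs").
 *
 * State ordering and parameter ordering MUST match stateTemplate() /
 * paramTemplate() on the R side; an independent per-reaction interpreter over
 * the ReactionNetwork object cross-checks the two in the test suite.
 *
 * Units: molecules/cell for cellular species, nM for medium/tumor drug and
 * ligand concentrations, mg and L for PK amounts/volumes, hours for time.
 */

#include <R.h>
#include <math.h>

#define NPAR 151

static double p[NPAR];

void initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* state indices */
#define iE1    0
#define iE2    1
#define iE3    2
#define iE4    3
#define iLE1   4
#define iNE3   5
#define iNE4   6
#define iD12   7
#define ipD12  8
#define iD22   9
#define ipD22 10
#define iD23  11
#define ipD23 12
#define iD32  13
#define ipD32 14
#define iD42  15
#define ipD42 16
#define iPI3K 17
#define ipPI3K 18
#define iAKT  19
#define ipAKT 20
#define iRAF  21
#define ipRAF 22
#define iERK  23
#define ipERK 24
#define iTHP1 25
#define iTHP2 26
#define iTHP4 27
#define iADC1 28
#define iCPX1 29
#define iINT1 30
#define iPIN1 31
#define iPEX1 32
#define iADC2 33
#define iCPX2 34
#define iINT2 35
#define iPIN2 36
#define iPEX2 37
#define iNCELL 38
#define iGLAP 39
#define iCLAPC 40
#define iCLAPP 41
#define iGPYR 42
#define iCPYRC 43
#define iCPYRP 44
#define iA1C  45
#define iA1P  46
#define iPL1C 47
#define iPL1P 48
#define iA2C  49
#define iA2P  50
#define iPL2C 51
#define iPL2P 52
#define iGCAP 53
#define iACAP 54
#define iDFCR 55
#define iDFUR 56
#define iAFU  57

/* parameter indices (order of paramTemplate()) */
#define ksyn1 p[0]
#define ksyn2 p[1]
#define ksyn3 p[2]
#define ksyn4 p[3]
#define kdeg1 p[4]
#define kdeg2 p[5]
#define kdeg3 p[6]
#define kdeg4 p[7]
#define kint_lig p[8]
#define fb_fold p[9]
#define km_fb p[10]
#define kEGFon p[11]
#define kEGFoff p[12]
#define k8on p[13]
#define k8off p[14]
#define kNRG4on p[15]
#define kNRG4off p[16]
#define kon12 p[17]
#define koff12 p[18]
#define kon22 p[19]
#define koff22 p[20]
#define kon23 p[21]
#define koff23 p[22]
#define kon32 p[23]
#define koff32 p[24]
#define kon42 p[25]
#define koff42 p[26]
#define kphos p[27]
#define kdeph p[28]
#define kon_PI3K p[29]
#define koff_PI3K p[30]
#define km_PI3K p[31]
#define n_PI3K p[32]
#define w_her3 p[33]
#define kon_AKT p[34]
#define koff_AKT p[35]
#define km_AKTact p[36]
#define n_AKTact p[37]
#define kon_Raf p[38]
#define koff_Raf p[39]
#define w7 p[40]
#define km7 p[41]
#define n7 p[42]
#define kon_ERK p[43]
#define koff_ERK p[44]
#define w8 p[45]
#define km8 p[46]
#define n8 p[47]
#define w11 p[48]
#define km11 p[49]
#define n11 p[50]
#define wAKT p[51]
#define km_AKTg p[52]
#define n_AKTg p[53]
#define w_basal p[54]
#define w_btk p[55]
#define km_btk p[56]
#define umax p[57]
#define dmax p[58]
#define km13 p[59]
#define n13 p[60]
#define w14_dm1 p[61]
#define km14_dm1 p[62]
#define n14_dm1 p[63]
#define w14_dxd p[64]
#define km14_dxd p[65]
#define n14_dxd p[66]
#define w15 p[67]
#define km10 p[68]
#define n10 p[69]
#define Vmax p[70]
#define cells_per_mm3 p[71]
#define Kd_lap p[72]
#define prot_lap p[73]
#define kinact_pyr p[74]
#define krec_pyr p[75]
#define degfold_lap p[76]
#define degfold_pyr p[77]
#define konA1 p[78]
#define koffA1 p[79]
#define kint_ADC1 p[80]
#define kdeg_ADC_2_1 p[81]
#define DAR1 p[82]
#define kout_PL p[83]
#define kelim_pex1 p[84]
#define konA2 p[85]
#define koffA2 p[86]
#define kint_ADC2 p[87]
#define kdeg_ADC_2_2 p[88]
#define DAR2 p[89]
#define kper_PL p[90]
#define kelim_pex2 p[91]
#define volfac p[92]
#define cellconv p[93]
#define ktu1 p[94]
#define kelim_tu1 p[95]
#define ktu2 p[96]
#define kelim_tu2 p[97]
#define bath_EGF p[98]
#define bath_NRG1 p[99]
#define bath_lap p[100]
#define bath_pyr p[101]
#define bath_FU p[102]
#define lap_ka p[103]
#define lap_CL p[104]
#define lap_Vc p[105]
#define lap_Q p[106]
#define lap_Vp p[107]
#define Kp_lap p[108]
#define pyr_ka p[109]
#define pyr_CL p[110]
#define pyr_Vc p[111]
#define pyr_Q p[112]
#define pyr_Vp p[113]
#define Kp_pyr p[114]
#define tdm1_CL p[115]
#define tdm1_Vc p[116]
#define tdm1_Q p[117]
#define tdm1_Vp p[118]
#define tdm1_krel p[119]
#define tdm1_CLpl p[120]
#define tdm1_Vcpl p[121]
#define tdm1_Qpl p[122]
#define tdm1_Vppl p[123]
#define tdxd_CL p[124]
#define tdxd_Vc p[125]
#define tdxd_Q p[126]
#define tdxd_Vp p[127]
#define tdxd_krel p[128]
#define tdxd_CLpl p[129]
#define tdxd_Vcpl p[130]
#define tdxd_Qpl p[131]
#define tdxd_Vppl p[132]
#define cap_ka p[133]
#define cap_k1 p[134]
#define cap_k2 p[135]
#define cap_k3 p[136]
#define cap_CL p[137]
#define cap_CLdfcr p[138]
#define cap_CLdfur p[139]
#define cap_CLfu p[140]
#define cap_V p[141]
#define cap_Vmet p[142]
#define Kp_FU p[143]
#define f_invitro p[144]
#define f_turnover p[145]
#define f_pk p[146]
#define w22 p[147]
#define krec_ADC1 p[148]
#define krec_ADC2 p[149]
#define w_her3_basal p[150]

/* mg/L -> nM conversion (1e6 / molecular weight in g/mol) */
#define CONV_LAP 1721.0
#define CONV_PYR 1715.0
#define CONV_FU  7688.0

static double hill(double x, double km, double n)
{
    double xn, kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    kn = pow(km, n);
    return xn / (kn + xn);
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    double C_lap, C_pyr, C_FU, EGF, NRG;
    double thL, thLp, thP1v, thP2v, thP4v;
    double th1, th2, th4p, th1p, th2p;
    double act12, act22, act23, act32, act42;
    double vEGF, vN3, vN4, v12, v22, v23, v32, v42;
    double vp12, vp22, vp23, vp32, vp42;
    double fbm, ft, S_raf, S_pi3k, hP, hA, hR, hE;
    double S_growth, V, gfac, mu, death;
    double vb1, vb2;

    ft = f_turnover;

    /* tumor/medium drug exposures */
    C_lap = bath_lap + f_pk * Kp_lap * (y[iCLAPC] / lap_Vc) * CONV_LAP;
    C_pyr = bath_pyr + f_pk * Kp_pyr * (y[iCPYRC] / pyr_Vc) * CONV_PYR;
    C_FU  = bath_FU  + f_pk * Kp_FU  * (y[iAFU] / cap_Vmet) * CONV_FU;
    EGF = bath_EGF;
    NRG = bath_NRG1;

    /* TKI occupancies: lapatinib reversible (equilibrium), pyrotinib covalent
     * (state). NRG1/EGF-bound dimers protect against lapatinib (prot_lap). */
    thL  = C_lap / (Kd_lap + C_lap);
    thLp = C_lap / (Kd_lap * prot_lap + C_lap);
    thP1v = y[iTHP1]; thP2v = y[iTHP2]; thP4v = y[iTHP4];
    th1  = thL  + thP1v - thL  * thP1v;
    th2  = thL  + thP2v - thL  * thP2v;
    th1p = thLp + thP1v - thLp * thP1v;
    th2p = thLp + thP2v - thLp * thP2v;
    th4p = thP4v;                       /* lapatinib does not bind HER4 */

    /* per-dimer kinase availability (HER3 kinase-dead; transphosphorylation
     * possible while at least one competent kinase is unoccupied) */
    act12 = 1.0 - th1p * th2p;
    act22 = 1.0 - th2 * th2;
    act23 = 1.0 - th2;
    act32 = 1.0 - th2p;
    act42 = 1.0 - th4p * th2p;

    /* ligand binding */
    vEGF = kEGFon * EGF * y[iE1] - kEGFoff * y[iLE1];
    vN3  = k8on   * NRG * y[iE3] - k8off   * y[iNE3];
    vN4  = kNRG4on * NRG * y[iE4] - kNRG4off * y[iNE4];

    /* dimerization */
    v12 = kon12 * y[iLE1] * y[iE2] - koff12 * y[iD12];
    v22 = kon22 * y[iE2] * y[iE2]  - koff22 * y[iD22];
    v23 = kon23 * y[iE2] * y[iE3]  - koff23 * y[iD23];
    v32 = kon32 * y[iNE3] * y[iE2] - koff32 * y[iD32];
    v42 = kon42 * y[iNE4] * y[iE2] - koff42 * y[iD42];

    /* transphosphorylation / dephosphorylation */
    vp12 = kphos * act12 * y[iD12] - kdeph * y[ipD12];
    vp22 = kphos * act22 * y[iD22] - kdeph * y[ipD22];
    vp23 = kphos * act23 * y[iD23] - kdeph * y[ipD23];
    vp32 = kphos * act32 * y[iD32] - kdeph * y[ipD32];
    vp42 = kphos * act42 * y[iD42] - kdeph * y[ipD42];

    /* FOXO feedback: low pAKT de-represses HER3 synthesis */
    fbm = 1.0 + fb_fold * km_fb / (km_fb + y[ipAKT]);

    /* ADC binding to surface HER2 */
    vb1 = konA1 * y[iADC1] * y[iE2] - koffA1 * y[iCPX1];
    vb2 = konA2 * y[iADC2] * y[iE2] - koffA2 * y[iCPX2];

    /* free receptors */
    ydot[iE1] = -vEGF
        + ft * (ksyn1 - kdeg1 * (1.0 + (degfold_lap - 1.0) * thL
                                     + (degfold_pyr - 1.0) * thP1v) * y[iE1]);
    ydot[iE2] = -v12 - 2.0 * v22 - v23 - v32 - v42 - vb1 - vb2
        + ft * (ksyn2 - kdeg2 * (1.0 + (degfold_lap - 1.0) * thL
                                     + (degfold_pyr - 1.0) * thP2v) * y[iE2]);
    ydot[iE3] = -vN3 - v23
        + ft * (ksyn3 * fbm - kdeg3 * y[iE3]);
    ydot[iE4] = -vN4
        + ft * (ksyn4 - kdeg4 * (1.0 + (degfold_pyr - 1.0) * thP4v) * y[iE4]);

    /* ligand-receptor complexes */
    ydot[iLE1] = vEGF - v12 - ft * kint_lig * y[iLE1];
    ydot[iNE3] = vN3  - v32 - ft * kint_lig * y[iNE3];
    ydot[iNE4] = vN4  - v42 - ft * kint_lig * y[iNE4];

    /* dimers (ligand-bound dimers internalize with the ligand) */
    ydot[iD12]  = v12 - vp12 - ft * kint_lig * y[iD12];
    ydot[ipD12] = vp12       - ft * kint_lig * y[ipD12];
    ydot[iD22]  = v22 - vp22;
    ydot[ipD22] = vp22;
    ydot[iD23]  = v23 - vp23;
    ydot[ipD23] = vp23;
    ydot[iD32]  = v32 - vp32 - ft * kint_lig * y[iD32];
    ydot[ipD32] = vp32       - ft * kint_lig * y[ipD32];
    ydot[iD42]  = v42 - vp42 - ft * kint_lig * y[iD42];
    ydot[ipD42] = vp42       - ft * kint_lig * y[ipD42];

    /* signaling drives */
    S_pi3k = w_her3 * (y[ipD32] + y[ipD42]) + w_her3_basal * y[ipD23]
             + y[ipD12] + w22 * 2.0 * y[ipD22];
    S_raf  = S_pi3k;   /* same HER3/HER4-weighted phospho-dimer drive */

    hP = hill(S_pi3k, km_PI3K, n_PI3K);
    ydot[iPI3K]  = -kon_PI3K * hP * y[iPI3K] + koff_PI3K * y[ipPI3K];
    ydot[ipPI3K] = -ydot[iPI3K];

    hA = hill(y[ipPI3K], km_AKTact, n_AKTact);
    ydot[iAKT]  = -kon_AKT * hA * y[iAKT] + koff_AKT * y[ipAKT];
    ydot[ipAKT] = -ydot[iAKT];

    hR = w7 * hill(S_raf, km7, n7);
    ydot[iRAF]  = -kon_Raf * hR * y[iRAF] + koff_Raf * y[ipRAF];
    ydot[ipRAF] = -ydot[iRAF];

    hE = w8 * hill(y[ipRAF], km8, n8);
    ydot[iERK]  = -kon_ERK * hE * y[iERK] + koff_ERK * y[ipERK];
    ydot[ipERK] = -ydot[iERK];

    /* pyrotinib covalent occupancy */
    ydot[iTHP1] = kinact_pyr * C_pyr * (1.0 - y[iTHP1]) - krec_pyr * y[iTHP1];
    ydot[iTHP2] = kinact_pyr * C_pyr * (1.0 - y[iTHP2]) - krec_pyr * y[iTHP2];
    ydot[iTHP4] = kinact_pyr * C_pyr * (1.0 - y[iTHP4]) - krec_pyr * y[iTHP4];

    /* ADC processing: T-DM1 (payload DM1, efflux only, no re-entry) */
    ydot[iADC1] = f_pk * (ktu1 * y[iA1C] - kelim_tu1 * y[iADC1]);
    ydot[iCPX1] = vb1 - kint_ADC1 * y[iCPX1];
    ydot[iINT1] = kint_ADC1 * y[iCPX1]
                  - ft * (kdeg_ADC_2_1 + krec_ADC1) * y[iINT1];
    ydot[iPIN1] = ft * kdeg_ADC_2_1 * y[iINT1] * DAR1 - kout_PL * y[iPIN1];
    ydot[iPEX1] = kout_PL * y[iPIN1] * cellconv - kelim_pex1 * y[iPEX1];

    /* T-DXd (payload DXd, bidirectional membrane permeation) */
    ydot[iADC2] = f_pk * (ktu2 * y[iA2C] - kelim_tu2 * y[iADC2]);
    ydot[iCPX2] = vb2 - kint_ADC2 * y[iCPX2];
    ydot[iINT2] = kint_ADC2 * y[iCPX2]
                  - ft * (kdeg_ADC_2_2 + krec_ADC2) * y[iINT2];
    ydot[iPIN2] = ft * kdeg_ADC_2_2 * y[iINT2] * DAR2
                  - kper_PL * (y[iPIN2] - y[iPEX2] * volfac);
    ydot[iPEX2] = kper_PL * (y[iPIN2] - y[iPEX2] * volfac) * cellconv
                  - kelim_pex2 * y[iPEX2];

    /* tumor growth/death */
    S_growth = (w11 * hill(y[ipERK], km11, n11)
                + wAKT * hill(y[ipAKT], km_AKTg, n_AKTg)
                + w_basal
                + w_btk * hill(NRG, km_btk, 1.0))
               / (w11 + wAKT + w_basal + w_btk);
    V = y[iNCELL] / cells_per_mm3;
    gfac = (f_invitro > 0.5) ? 1.0 : (1.0 - V / Vmax);
    mu = (umax / 24.0) * hill(S_growth, km13, n13) * gfac;
    death = (dmax / 24.0) * (1.0
        + w14_dm1 * hill(y[iPIN1], km14_dm1, n14_dm1)
        + w14_dxd * hill(y[iPIN2], km14_dxd, n14_dxd)
        + w15 * hill(C_FU, km10, n10));
    ydot[iNCELL] = y[iNCELL] * (mu - death);

    /* PK: lapatinib (oral, 2-compartment) */
    ydot[iGLAP]  = -lap_ka * y[iGLAP];
    ydot[iCLAPC] = lap_ka * y[iGLAP] - lap_CL * (y[iCLAPC] / lap_Vc)
                   - lap_Q * (y[iCLAPC] / lap_Vc - y[iCLAPP] / lap_Vp);
    ydot[iCLAPP] = lap_Q * (y[iCLAPC] / lap_Vc - y[iCLAPP] / lap_Vp);

    /* PK: pyrotinib */
    ydot[iGPYR]  = -pyr_ka * y[iGPYR];
    ydot[iCPYRC] = pyr_ka * y[iGPYR] - pyr_CL * (y[iCPYRC] / pyr_Vc)
                   - pyr_Q * (y[iCPYRC] / pyr_Vc - y[iCPYRP] / pyr_Vp);
    ydot[iCPYRP] = pyr_Q * (y[iCPYRC] / pyr_Vc - y[iCPYRP] / pyr_Vp);

    /* PK: T-DM1 conjugate + released-payload disposition */
    ydot[iA1C]  = -tdm1_CL * (y[iA1C] / tdm1_Vc) - tdm1_krel * y[iA1C]
                  - tdm1_Q * (y[iA1C] / tdm1_Vc - y[iA1P] / tdm1_Vp);
    ydot[iA1P]  = tdm1_Q * (y[iA1C] / tdm1_Vc - y[iA1P] / tdm1_Vp);
    ydot[iPL1C] = tdm1_krel * y[iA1C] - tdm1_CLpl * (y[iPL1C] / tdm1_Vcpl)
                  - tdm1_Qpl * (y[iPL1C] / tdm1_Vcpl - y[iPL1P] / tdm1_Vppl);
    ydot[iPL1P] = tdm1_Qpl * (y[iPL1C] / tdm1_Vcpl - y[iPL1P] / tdm1_Vppl);

    /* PK: T-DXd */
    ydot[iA2C]  = -tdxd_CL * (y[iA2C] / tdxd_Vc) - tdxd_krel * y[iA2C]
                  - tdxd_Q * (y[iA2C] / tdxd_Vc - y[iA2P] / tdxd_Vp);
    ydot[iA2P]  = tdxd_Q * (y[iA2C] / tdxd_Vc - y[iA2P] / tdxd_Vp);
    ydot[iPL2C] = tdxd_krel * y[iA2C] - tdxd_CLpl * (y[iPL2C] / tdxd_Vcpl)
                  - tdxd_Qpl * (y[iPL2C] / tdxd_Vcpl - y[iPL2P] / tdxd_Vppl);
    ydot[iPL2P] = tdxd_Qpl * (y[iPL2C] / tdxd_Vcpl - y[iPL2P] / tdxd_Vppl);

    /* PK: capecitabine -> 5'DFCR -> 5'DFUR -> 5-FU */
    ydot[iGCAP] = -cap_ka * y[iGCAP];
    ydot[iACAP] = cap_ka * y[iGCAP] - cap_k1 * y[iACAP]
                  - cap_CL * (y[iACAP] / cap_V);
    ydot[iDFCR] = cap_k1 * y[iACAP] - cap_k2 * y[iDFCR]
                  - cap_CLdfcr * (y[iDFCR] / cap_Vmet);
    ydot[iDFUR] = cap_k2 * y[iDFCR] - cap_k3 * y[iDFUR]
                  - cap_CLdfur * (y[iDFUR] / cap_Vmet);
    ydot[iAFU]  = cap_k3 * y[iDFUR] - cap_CLfu * (y[iAFU] / cap_Vmet);
}
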