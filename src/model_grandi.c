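/* Grandi, Pasqualini & Bers 2010 human ventricular myocyte model,
 * epicardial variant.  39 state variables; mV, ms, mM.  Two sarcolemmal
 * compartments (junctional cleft and bulk subsarcolemmal space) plus bulk
 * cytosol; Ki and Cli are held constant as in the published code.
 *
 * State layout:
 *  0 V    1 m    2 h    3 j    4 d    5 f    6 fcaBj 7 fcaBsl
 *  8 xtos 9 ytos 10 xtof 11 ytof 12 xkr 13 xks
 * 14 RyRr 15 RyRo 16 RyRi 17 NaBj 18 NaBsl
 * 19 TnCL 20 TnCHc 21 TnCHm 22 CaM 23 Myoc 24 Myom 25 SRB
 * 26 SLLj 27 SLLsl 28 SLHj 29 SLHsl 30 Csqnb
 * 31 Casr 32 Naj 33 Nasl 34 Nai 35 Ki 36 Caj 37 Casl 38 Cai
 */
#include "qtsim.h"

void qtsim_rhs_grandi(double t, const double *y, const double *p, double *dy)
{
    const double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4], f = y[5],
                 fcaBj = y[6], fcaBsl = y[7], xtos = y[8], ytos = y[9],
                 xtof = y[10], ytof = y[11], xkr = y[12], xks = y[13],
                 RyRr = y[14], RyRo = y[15], RyRi = y[16], NaBj = y[17],
                 NaBsl = y[18], TnCL = y[19], TnCHc = y[20], TnCHm = y[21],
                 CaM = y[22], Myoc = y[23], Myom = y[24], SRB = y[25],
                 SLLj = y[26], SLLsl = y[27], SLHj = y[28], SLHsl = y[29],
                 Csqnb = y[30], Casr = y[31], Naj = y[32], Nasl = y[33],
                 Nai = y[34], Ki = y[35], Caj = y[36], Casl = y[37],
                 Cai = y[38];

    const double Frdy = 96485.0, Rgas = 8314.0, Temp = 310.0;
    const double FoRT = Frdy / (Rgas * Temp);
    const double Cmem = 1.3810e-10;      /* F */
    const double Qpow = 0.0;             /* (T-310)/10 */

    /* geometry (volumes in L) */
    const double pi_ = 3.141592653589793;
    const double cellLength = 100.0, cellRadius = 10.25;
    const double Vcell = pi_ * cellRadius * cellRadius * cellLength * 1.0e-15;
    const double Vmyo = 0.65 * Vcell, Vsr = 0.035 * Vcell,
                 Vsl = 0.02 * Vcell, Vjunc = 0.0539 * 0.01 * Vcell;
    const double J_ca_juncsl = 1.0 / 1.2134e12;
    const double J_ca_slmyo = 1.0 / 2.68510e11;
    const double J_na_juncsl = 1.0 / (1.6382e12 / 3.0 * 100.0);
    const double J_na_slmyo = 1.0 / (1.8308e10 / 3.0 * 100.0);

    const double Fjunc = 0.11, Fsl = 1.0 - Fjunc;
    const double Fjunc_CaL = 0.9, Fsl_CaL = 0.1;

    const double Cli = 15.0, Clo = 150.0;
    const double Ko = 5.4, Nao = 140.0, Cao = 1.8;
    const double Mgi = 1.0;

    const double ena_junc = (1.0 / FoRT) * log(Nao / Naj);
    const double ena_sl = (1.0 / FoRT) * log(Nao / Nasl);
    const double ek = (1.0 / FoRT) * log(Ko / Ki);
    const double eca_junc = (1.0 / FoRT / 2.0) * log(Cao / Caj);
    const double eca_sl = (1.0 / FoRT / 2.0) * log(Cao / Casl);
    const double ecl = (1.0 / FoRT) * log(Cli / Clo);

    /* INa */
    const double GNa = 23.0 * p[SC_INA];
    double tmp = 1.0 + exp(-(56.86 + V) / 9.03);
    const double mss = 1.0 / (tmp * tmp);
    const double taum = 0.1292 * exp(-((V + 45.79) / 15.54)
                                     * ((V + 45.79) / 15.54))
                      + 0.06487 * exp(-((V - 4.823) / 51.12)
                                      * ((V - 4.823) / 51.12));
    double ah, bh, aj, bj;
    if (V >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    } else {
        ah = 0.057 * exp(-(V + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
        aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V))
             * (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    const double tauh = 1.0 / (ah + bh);
    tmp = 1.0 + exp((V + 71.55) / 7.43);
    const double hss = 1.0 / (tmp * tmp);
    const double tauj = 1.0 / (aj + bj);
    const double jss = hss;
    dy[1] = (mss - m) / taum;
    dy[2] = (hss - h) / tauh;
    dy[3] = (jss - j) / tauj;
    const double I_Na_junc = Fjunc * GNa * m * m * m * h * j * (V - ena_junc);
    const double I_Na_sl = Fsl * GNa * m * m * m * h * j * (V - ena_sl);

    /* background Na */
    const double GNaB = 0.597e-3;
    const double I_nabk_junc = Fjunc * GNaB * (V - ena_junc);
    const double I_nabk_sl = Fsl * GNaB * (V - ena_sl);

    /* INaK */
    const double IbarNaK = 1.8, KmNaip = 11.0, KmKo = 1.5;
    const double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
    const double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V * FoRT)
                               + 0.0365 * sigma * exp(-V * FoRT));
    double kmnaip4 = KmNaip / Naj;
    kmnaip4 *= kmnaip4; kmnaip4 *= kmnaip4;
    const double I_nak_junc = Fjunc * IbarNaK * fnak * Ko
                              / (1.0 + kmnaip4) / (Ko + KmKo);
    double kmnaip4s = KmNaip / Nasl;
    kmnaip4s *= kmnaip4s; kmnaip4s *= kmnaip4s;
    const double I_nak_sl = Fsl * IbarNaK * fnak * Ko
                            / (1.0 + kmnaip4s) / (Ko + KmKo);
    const double I_nak = I_nak_junc + I_nak_sl;

    /* IKr */
    const double gkr = 0.035 * sqrt(Ko / 5.4) * p[SC_IKR];
    const double xrss = 1.0 / (1.0 + exp(-(V + 10.0) / 5.0));
    const double tauxr = 550.0 / (1.0 + exp((-22.0 - V) / 9.0))
                         * 6.0 / (1.0 + exp((V + 11.0) / 9.0))
                         + 230.0 / (1.0 + exp((V + 40.0) / 20.0));
    dy[12] = (xrss - xkr) / tauxr;
    const double rkr = 1.0 / (1.0 + exp((V + 74.0) / 24.0));
    const double I_kr = gkr * xkr * rkr * (V - ek);

    /* IKs */
    const double pNaK = 0.01833;
    const double eks = (1.0 / FoRT) * log((Ko + pNaK * Nao)
                                          / (Ki + pNaK * Nai));
    const double gks = 0.0035 * p[SC_IKS];
    const double xsss = 1.0 / (1.0 + exp(-(V + 3.8) / 14.25));
    const double tauxs = 990.1 / (1.0 + exp(-(V + 2.436) / 14.12));
    dy[13] = (xsss - xks) / tauxs;
    const double I_ks_junc = Fjunc * gks * xks * xks * (V - eks);
    const double I_ks_sl = Fsl * gks * xks * xks * (V - eks);
    const double I_ks = I_ks_junc + I_ks_sl;

    /* IKp (plateau K) */
    const double gkp = 0.002;
    const double kp_kp = 1.0 / (1.0 + exp(7.488 - V / 5.98));
    const double I_kp = gkp * kp_kp * (V - ek);

    /* Ito: distinct slow and fast components; the Kv4.3 screen maps onto
     * the fast component only, so the block handle scales GtoFast alone. */
    const double GtoSlow = 0.13 * 0.12;          /* epi */
    const double GtoFast = 0.13 * 0.88 * p[SC_ITO];
    const double xtoss = 1.0 / (1.0 + exp(-(V - 19.0) / 13.0));
    const double ytoss = 1.0 / (1.0 + exp((V + 19.5) / 5.0));
    const double tauxtos = 9.0 / (1.0 + exp((V + 3.0) / 15.0)) + 0.5;
    const double tauytos = 800.0 / (1.0 + exp((V + 60.0) / 10.0)) + 30.0;
    const double tauxtof = 8.5 * exp(-((V + 45.0) / 50.0)
                                     * ((V + 45.0) / 50.0)) + 0.5;
    const double tauytof = 85.0 * exp(-(V + 40.0) * (V + 40.0) / 220.0) + 7.0;
    dy[8] = (xtoss - xtos) / tauxtos;
    dy[9] = (ytoss - ytos) / tauytos;
    dy[10] = (xtoss - xtof) / tauxtof;
    dy[11] = (ytoss - ytof) / tauytof;
    const double I_tos = GtoSlow * xtos * ytos * (V - ek);
    const double I_tof = GtoFast * xtof * ytof * (V - ek);
    const double I_to = I_tos + I_tof;

    /* IK1 */
    const double aki = 1.02 / (1.0 + exp(0.2385 * (V - ek - 59.215)));
    const double bki = (0.49124 * exp(0.08032 * (V + 5.476 - ek))
                        + exp(0.06175 * (V - ek - 594.31)))
                       / (1.0 + exp(-0.5143 * (V - ek + 4.753)));
    const double kiss = aki / (aki + bki);
    const double I_ki = 0.35 * sqrt(Ko / 5.4) * kiss * (V - ek) * p[SC_IK1];

    /* Ca-activated Cl and background Cl */
    const double GClCa = 0.5 * 0.109625, KdClCa = 100.0e-3, GClB = 9.0e-3;
    const double I_ClCa_junc = Fjunc * GClCa / (1.0 + KdClCa / Caj)
                               * (V - ecl);
    const double I_ClCa_sl = Fsl * GClCa / (1.0 + KdClCa / Casl) * (V - ecl);
    const double I_ClCa = I_ClCa_junc + I_ClCa_sl;
    const double I_Clbk = GClB * (V - ecl);

    /* ICaL (GHK) */
    const double pNa = 0.50 * 1.5e-8 * p[SC_ICAL];
    const double pCa = 0.50 * 5.4e-4 * p[SC_ICAL];
    const double pK = 0.50 * 2.7e-7 * p[SC_ICAL];
    const double dss = 1.0 / (1.0 + exp(-(V + 5.0) / 6.0));
    double taud;
    if (fabs(V + 5.0) < 1e-6)
        taud = dss / 0.035 / 6.0; /* limit of dss*(1-e^-x)/(0.035*6x) * 6 */
    else
        taud = dss * (1.0 - exp(-(V + 5.0) / 6.0)) / (0.035 * (V + 5.0));
    const double fss = 1.0 / (1.0 + exp((V + 35.0) / 9.0))
                       + 0.6 / (1.0 + exp((50.0 - V) / 20.0));
    const double tauf = 1.0 / (0.0197
        * exp(-(0.0337 * (V + 14.5)) * (0.0337 * (V + 14.5))) + 0.02);
    dy[4] = (dss - d) / taud;
    dy[5] = (fss - f) / tauf;
    dy[6] = 1.7 * Caj * (1.0 - fcaBj) - 11.9e-3 * fcaBj;
    dy[7] = 1.7 * Casl * (1.0 - fcaBsl) - 11.9e-3 * fcaBsl;
    const double ex2 = exp(2.0 * V * FoRT), ex1 = exp(V * FoRT);
    double ibarca_j, ibarca_sl, ibark, ibarna_j, ibarna_sl;
    if (fabs(V) < 1e-7) {
        ibarca_j = pCa * 2.0 * Frdy * (0.341 * Caj * ex2 - 0.341 * Cao)
                   / (1.0 + V * FoRT);
        ibarca_sl = pCa * 2.0 * Frdy * (0.341 * Casl * ex2 - 0.341 * Cao)
                    / (1.0 + V * FoRT);
        ibark = pK * Frdy * (0.75 * Ki * ex1 - 0.75 * Ko)
                / (1.0 + 0.5 * V * FoRT);
        ibarna_j = pNa * Frdy * (0.75 * Naj * ex1 - 0.75 * Nao)
                   / (1.0 + 0.5 * V * FoRT);
        ibarna_sl = pNa * Frdy * (0.75 * Nasl * ex1 - 0.75 * Nao)
                    / (1.0 + 0.5 * V * FoRT);
    } else {
        ibarca_j = pCa * 4.0 * (V * Frdy * FoRT)
                   * (0.341 * Caj * ex2 - 0.341 * Cao) / (ex2 - 1.0);
        ibarca_sl = pCa * 4.0 * (V * Frdy * FoRT)
                    * (0.341 * Casl * ex2 - 0.341 * Cao) / (ex2 - 1.0);
        ibark = pK * (V * Frdy * FoRT)
                * (0.75 * Ki * ex1 - 0.75 * Ko) / (ex1 - 1.0);
        ibarna_j = pNa * (V * Frdy * FoRT)
                   * (0.75 * Naj * ex1 - 0.75 * Nao) / (ex1 - 1.0);
        ibarna_sl = pNa * (V * Frdy * FoRT)
                    * (0.75 * Nasl * ex1 - 0.75 * Nao) / (ex1 - 1.0);
    }
    const double Q10CaL = 1.8;
    const double qcal = pow(Q10CaL, Qpow) * 0.45;
    const double I_Ca_junc = Fjunc_CaL * ibarca_j * d * f * (1.0 - fcaBj)
                             * qcal;
    const double I_Ca_sl = Fsl_CaL * ibarca_sl * d * f * (1.0 - fcaBsl)
                           * qcal;
    const double I_CaK = ibark * d * f
        * (Fjunc_CaL * (1.0 - fcaBj) + Fsl_CaL * (1.0 - fcaBsl)) * qcal;
    const double I_CaNa_junc = Fjunc_CaL * ibarna_j * d * f * (1.0 - fcaBj)
                               * qcal;
    const double I_CaNa_sl = Fsl_CaL * ibarna_sl * d * f * (1.0 - fcaBsl)
                             * qcal;

    /* INCX */
    const double IbarNCX = 4.5, KmCai = 3.59e-3, KmCao = 1.3,
                 KmNai = 12.29, KmNao = 87.5, ksat = 0.32, nu = 0.27,
                 Kdact = 0.150e-3, Q10NCX = 1.57;
    const double qncx = pow(Q10NCX, Qpow);
    const double Ka_junc = 1.0 / (1.0 + (Kdact / Caj) * (Kdact / Caj));
    const double Ka_sl = 1.0 / (1.0 + (Kdact / Casl) * (Kdact / Casl));
    const double Naj3 = Naj * Naj * Naj, Nasl3 = Nasl * Nasl * Nasl,
                 Nao3 = Nao * Nao * Nao,
                 KmNai3 = KmNai * KmNai * KmNai,
                 KmNao3 = KmNao * KmNao * KmNao;
    const double s1_junc = exp(nu * V * FoRT) * Naj3 * Cao;
    const double s2_junc = exp((nu - 1.0) * V * FoRT) * Nao3 * Caj;
    const double s3_junc = KmCai * Nao3 * (1.0 + Naj3 / KmNai3)
        + KmNao3 * Caj * (1.0 + Caj / KmCai) + KmCao * Naj3
        + Naj3 * Cao + Nao3 * Caj;
    const double I_ncx_junc = Fjunc * IbarNCX * qncx * Ka_junc
        * (s1_junc - s2_junc) / s3_junc
        / (1.0 + ksat * exp((nu - 1.0) * V * FoRT));
    const double s1_sl = exp(nu * V * FoRT) * Nasl3 * Cao;
    const double s2_sl = exp((nu - 1.0) * V * FoRT) * Nao3 * Casl;
    const double s3_sl = KmCai * Nao3 * (1.0 + Nasl3 / KmNai3)
        + KmNao3 * Casl * (1.0 + Casl / KmCai) + KmCao * Nasl3
        + Nasl3 * Cao + Nao3 * Casl;
    const double I_ncx_sl = Fsl * IbarNCX * qncx * Ka_sl
        * (s1_sl - s2_sl) / s3_sl
        / (1.0 + ksat * exp((nu - 1.0) * V * FoRT));

    /* sarcolemmal Ca pump and background Ca */
    const double IbarSLCaP = 0.0673, KmPCa = 0.5e-3;
    const double kmpca16 = pow(KmPCa, 1.6);
    const double I_pca_junc = Fjunc * IbarSLCaP * pow(Caj, 1.6)
                              / (kmpca16 + pow(Caj, 1.6));
    const double I_pca_sl = Fsl * IbarSLCaP * pow(Casl, 1.6)
                            / (kmpca16 + pow(Casl, 1.6));
    const double GCaB = 5.513e-4;
    const double I_cabk_junc = Fjunc * GCaB * (V - eca_junc);
    const double I_cabk_sl = Fsl * GCaB * (V - eca_sl);

    /* SR fluxes: release (RyR), SERCA uptake, passive leak */
    const double Vmax_SRCaP = 5.3114e-3, Kmf = 0.246e-3, Kmr = 1.7,
                 hillSRCaP = 1.787, ks_ryr = 25.0, koCa = 10.0, kom = 0.06,
                 kiCa = 0.5, kim = 0.005, ec50SR = 0.45,
                 MaxSR = 15.0, MinSR = 1.0;
    const double kCaSR = MaxSR - (MaxSR - MinSR)
                         / (1.0 + pow(ec50SR / Casr, 2.5));
    const double koSRCa = koCa / kCaSR;
    const double kiSRCa = kiCa * kCaSR;
    const double RI = 1.0 - RyRr - RyRo - RyRi;
    dy[14] = (kim * RI - kiSRCa * Caj * RyRr)
             - (koSRCa * Caj * Caj * RyRr - kom * RyRo);
    dy[15] = (koSRCa * Caj * Caj * RyRr - kom * RyRo)
             - (kiSRCa * Caj * RyRo - kim * RyRi);
    dy[16] = (kiSRCa * Caj * RyRo - kim * RyRi)
             - (kom * RyRi - koSRCa * Caj * Caj * RI);
    const double J_SRCarel = ks_ryr * RyRo * (Casr - Caj);
    const double cf = pow(Cai / Kmf, hillSRCaP),
                 cr = pow(Casr / Kmr, hillSRCaP);
    const double J_serca = Vmax_SRCaP * (cf - cr) / (1.0 + cf + cr);
    const double J_SRleak = 5.348e-6 * (Casr - Caj);

    /* Na buffering */
    const double Bmax_Naj = 7.561, Bmax_Nasl = 1.65,
                 koff_na = 1.0e-3, kon_na = 0.1e-3;
    dy[17] = kon_na * Naj * (Bmax_Naj - NaBj) - koff_na * NaBj;
    dy[18] = kon_na * Nasl * (Bmax_Nasl - NaBsl) - koff_na * NaBsl;

    /* cytosolic Ca buffers */
    const double Bmax_TnClow = 70.0e-3, koff_tncl = 19.6e-3, kon_tncl = 32.7;
    const double Bmax_TnChigh = 140.0e-3, koff_tnchca = 0.032e-3,
                 kon_tnchca = 2.37, koff_tnchmg = 3.33e-3, kon_tnchmg = 3.0e-3;
    const double Bmax_CaM = 24.0e-3, koff_cam = 238.0e-3, kon_cam = 34.0;
    const double Bmax_myosin = 140.0e-3, koff_myoca = 0.46e-3,
                 kon_myoca = 13.8, koff_myomg = 0.057e-3, kon_myomg = 0.0157;
    const double Bmax_SR = 19.0 * 0.9e-3, koff_sr = 60.0e-3, kon_sr = 100.0;
    dy[19] = kon_tncl * Cai * (Bmax_TnClow - TnCL) - koff_tncl * TnCL;
    dy[20] = kon_tnchca * Cai * (Bmax_TnChigh - TnCHc - TnCHm)
             - koff_tnchca * TnCHc;
    dy[21] = kon_tnchmg * Mgi * (Bmax_TnChigh - TnCHc - TnCHm)
             - koff_tnchmg * TnCHm;
    dy[22] = kon_cam * Cai * (Bmax_CaM - CaM) - koff_cam * CaM;
    dy[23] = kon_myoca * Cai * (Bmax_myosin - Myoc - Myom)
             - koff_myoca * Myoc;
    dy[24] = kon_myomg * Mgi * (Bmax_myosin - Myoc - Myom)
             - koff_myomg * Myom;
    dy[25] = kon_sr * Cai * (Bmax_SR - SRB) - koff_sr * SRB;
    const double J_CaB_cytosol = dy[19] + dy[20] + dy[22] + dy[23] + dy[25];

    /* junctional and SL membrane Ca buffers */
    const double Bmax_SLlowsl = 37.4e-3 * Vmyo / Vsl,
                 Bmax_SLlowj = 4.6e-3 * Vmyo / Vjunc * 0.1,
                 koff_sll = 1300.0e-3, kon_sll = 100.0,
                 Bmax_SLhighsl = 13.4e-3 * Vmyo / Vsl,
                 Bmax_SLhighj = 1.65e-3 * Vmyo / Vjunc * 0.1,
                 koff_slh = 30.0e-3, kon_slh = 100.0;
    dy[26] = kon_sll * Caj * (Bmax_SLlowj - SLLj) - koff_sll * SLLj;
    dy[27] = kon_sll * Casl * (Bmax_SLlowsl - SLLsl) - koff_sll * SLLsl;
    dy[28] = kon_slh * Caj * (Bmax_SLhighj - SLHj) - koff_slh * SLHj;
    dy[29] = kon_slh * Casl * (Bmax_SLhighsl - SLHsl) - koff_slh * SLHsl;
    const double J_CaB_junction = dy[26] + dy[28];
    const double J_CaB_sl = dy[27] + dy[29];

    /* SR Ca buffer (calsequestrin) */
    const double Bmax_Csqn = 140.0e-3 * Vmyo / Vsr,
                 koff_csqn = 65.0, kon_csqn = 100.0;
    dy[30] = kon_csqn * Casr * (Bmax_Csqn - Csqnb) - koff_csqn * Csqnb;
    dy[31] = J_serca - (J_SRleak * Vmyo / Vsr + J_SRCarel) - dy[30];

    /* sodium concentrations */
    const double I_Na_tot_junc = I_Na_junc + I_nabk_junc + 3.0 * I_ncx_junc
                                 + 3.0 * I_nak_junc + I_CaNa_junc;
    const double I_Na_tot_sl = I_Na_sl + I_nabk_sl + 3.0 * I_ncx_sl
                               + 3.0 * I_nak_sl + I_CaNa_sl;
    dy[32] = -I_Na_tot_junc * Cmem / (Vjunc * Frdy)
             + J_na_juncsl / Vjunc * (Nasl - Naj) - dy[17];
    dy[33] = -I_Na_tot_sl * Cmem / (Vsl * Frdy)
             + J_na_juncsl / Vsl * (Naj - Nasl)
             + J_na_slmyo / Vsl * (Nai - Nasl) - dy[18];
    dy[34] = J_na_slmyo / Vmyo * (Nasl - Nai);

    /* potassium held constant (as in the published code) */
    dy[35] = 0.0;

    /* calcium concentrations */
    const double I_Ca_tot_junc = I_Ca_junc + I_cabk_junc + I_pca_junc
                                 - 2.0 * I_ncx_junc;
    const double I_Ca_tot_sl = I_Ca_sl + I_cabk_sl + I_pca_sl
                               - 2.0 * I_ncx_sl;
    dy[36] = -I_Ca_tot_junc * Cmem / (Vjunc * 2.0 * Frdy)
             + J_ca_juncsl / Vjunc * (Casl - Caj) - J_CaB_junction
             + J_SRCarel * Vsr / Vjunc + J_SRleak * Vmyo / Vjunc;
    dy[37] = -I_Ca_tot_sl * Cmem / (Vsl * 2.0 * Frdy)
             + J_ca_juncsl / Vsl * (Caj - Casl)
             + J_ca_slmyo / Vsl * (Cai - Casl) - J_CaB_sl;
    dy[38] = -J_serca * Vsr / Vmyo - J_CaB_cytosol
             + J_ca_slmyo / Vmyo * (Casl - Cai);

    /* membrane potential */
    const double I_Na_tot = I_Na_tot_junc + I_Na_tot_sl;
    const double I_Cl_tot = I_ClCa + I_Clbk;
    const double I_Ca_tot = I_Ca_tot_junc + I_Ca_tot_sl;
    const double I_K_tot = I_to + I_kr + I_ks + I_ki - 2.0 * I_nak + I_CaK
                           + I_kp;
    const double Istim = qtsim_stim(t, p);
    dy[0] = -(I_Na_tot + I_Cl_tot + I_Ca_tot + I_K_tot + Istim);
}
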