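/* O'Hara, Virag, Varro & Rudy 2011 human ventricular myocyte model,
 * endocardial variant.  41 state variables; mV, ms, mM.
 *
 * State layout:
 *  0 V     1 Nai   2 Nass  3 Ki    4 Kss   5 Cai   6 Cass  7 Cansr 8 Cajsr
 *  9 m    10 hf   11 hs   12 j    13 hsp  14 jp   15 mL   16 hL   17 hLp
 * 18 a    19 iF   20 iS   21 ap   22 iFp  23 iSp  24 d    25 ff   26 fs
 * 27 fcaf 28 fcas 29 jca  30 nca  31 ffp  32 fcafp 33 xrf 34 xrs  35 xs1
 * 36 xs2  37 xk1  38 Jrelnp 39 Jrelp 40 CaMKt
 */
#include "qtsim.h"

void qtsim_rhs_ohara(double t, const double *y, const double *p, double *dy)
{
    const double V = y[0], Nai = y[1], Nass = y[2], Ki = y[3], Kss = y[4],
                 Cai = y[5], Cass = y[6], Cansr = y[7], Cajsr = y[8];
    const double m = y[9], hf = y[10], hs = y[11], j = y[12], hsp = y[13],
                 jp = y[14], mL = y[15], hL = y[16], hLp = y[17];
    const double a = y[18], iF = y[19], iS = y[20], ap = y[21], iFp = y[22],
                 iSp = y[23];
    const double d = y[24], ff = y[25], fs = y[26], fcaf = y[27],
                 fcas = y[28], jca = y[29], nca = y[30], ffp = y[31],
                 fcafp = y[32];
    const double xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36],
                 xk1 = y[37], Jrelnp = y[38], Jrelp = y[39], CaMKt = y[40];

    const double Nao = 140.0, Cao = 1.8, Ko = 5.4;
    const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

    /* cell geometry */
    const double L = 0.01, rad = 0.0011;
    const double vcell = 1000.0 * 3.14 * rad * rad * L;
    const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    const double Acap = 2.0 * Ageo;
    const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
                 vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    /* CaMK */
    const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068,
                 CaMKo = 0.05, KmCaM = 0.0015;
    const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / Cass);
    const double CaMKa = CaMKb + CaMKt;
    dy[40] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
    const double fphos = 1.0 / (1.0 + KmCaMK / CaMKa); /* CaMK-phosphorylated
                                                          fraction, shared */

    const double ENa = (Rgas * Temp / Frdy) * log(Nao / Nai);
    const double EK  = (Rgas * Temp / Frdy) * log(Ko / Ki);
    const double PKNa = 0.01833;
    const double EKs = (Rgas * Temp / Frdy)
                       * log((Ko + PKNa * Nao) / (Ki + PKNa * Nai));
    const double vffrt = V * Frdy * Frdy / (Rgas * Temp);
    const double vfrt  = V * Frdy / (Rgas * Temp);

    /* INa (fast) */
    const double mss = 1.0 / (1.0 + exp(-(V + 39.57) / 9.871));
    const double tm = 1.0 / (6.765 * exp((V + 11.64) / 34.77)
                             + 8.552 * exp(-(V + 77.42) / 5.955));
    const double hss = 1.0 / (1.0 + exp((V + 82.90) / 6.086));
    const double thf = 1.0 / (1.432e-5 * exp(-(V + 1.196) / 6.285)
                              + 6.149 * exp((V + 0.5096) / 20.27));
    const double ths = 1.0 / (0.009794 * exp(-(V + 17.95) / 28.05)
                              + 0.3343 * exp((V + 5.730) / 56.66));
    const double Ahf = 0.99, Ahs = 1.0 - Ahf;
    const double h = Ahf * hf + Ahs * hs;
    const double jss = hss;
    const double tj = 2.038 + 1.0 / (0.02136 * exp(-(V + 100.6) / 8.281)
                                     + 0.3052 * exp((V + 0.9941) / 38.45));
    const double hssp = 1.0 / (1.0 + exp((V + 89.1) / 6.086));
    const double thsp = 3.0 * ths;
    const double hp = Ahf * hf + Ahs * hsp;
    const double tjp = 1.46 * tj;
    const double GNa = 75.0 * p[SC_INA];
    const double INa = GNa * (V - ENa) * m * m * m
                       * ((1.0 - fphos) * h * j + fphos * hp * jp);
    dy[9]  = (mss - m) / tm;
    dy[10] = (hss - hf) / thf;
    dy[11] = (hss - hs) / ths;
    dy[12] = (jss - j) / tj;
    dy[13] = (hssp - hsp) / thsp;
    dy[14] = (jss - jp) / tjp;

    /* INaL (late sodium; not a screened channel, no scale handle) */
    const double mLss = 1.0 / (1.0 + exp(-(V + 42.85) / 5.264));
    const double tmL = tm;
    const double hLss = 1.0 / (1.0 + exp((V + 87.61) / 7.488));
    const double thL = 200.0;
    const double hLssp = 1.0 / (1.0 + exp((V + 93.81) / 7.488));
    const double thLp = 3.0 * thL;
    const double GNaL = 0.0075; /* endo */
    const double INaL = GNaL * (V - ENa) * mL
                        * ((1.0 - fphos) * hL + fphos * hLp);
    dy[15] = (mLss - mL) / tmL;
    dy[16] = (hLss - hL) / thL;
    dy[17] = (hLssp - hLp) / thLp;

    /* Ito */
    const double ass = 1.0 / (1.0 + exp(-(V - 14.34) / 14.82));
    const double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(V - 18.4099) / 29.3814)))
                                + 3.5 / (1.0 + exp((V + 100.0) / 29.3814)));
    const double iss = 1.0 / (1.0 + exp((V + 43.94) / 5.711));
    const double delta_epi = 1.0; /* endocardial */
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(V + 100.0) / 100.0)
                                + 0.08004 * exp((V + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(V + 96.52) / 59.05)
                                + 1.780e-8 * exp((V + 114.1) / 8.079));
    tiF *= delta_epi;
    tiS *= delta_epi;
    const double AiF = 1.0 / (1.0 + exp((V - 213.6) / 151.2));
    const double AiS = 1.0 - AiF;
    const double i_gate = AiF * iF + AiS * iS;
    const double assp = 1.0 / (1.0 + exp(-(V - 24.34) / 14.82));
    const double dti_develop = 1.354 + 1.0e-4
        / (exp((V - 167.4) / 15.89) + exp(-(V - 12.23) / 0.2154));
    const double dti_recover = 1.0 - 0.5 / (1.0 + exp((V + 70.0) / 20.0));
    const double tiFp = dti_develop * dti_recover * tiF;
    const double tiSp = dti_develop * dti_recover * tiS;
    const double ip_gate = AiF * iFp + AiS * iSp;
    const double Gto = 0.02 * p[SC_ITO]; /* endo */
    const double Ito = Gto * (V - EK)
                       * ((1.0 - fphos) * a * i_gate + fphos * ap * ip_gate);
    dy[18] = (ass - a) / ta;
    dy[19] = (iss - iF) / tiF;
    dy[20] = (iss - iS) / tiS;
    dy[21] = (assp - ap) / ta;
    dy[22] = (iss - iFp) / tiFp;
    dy[23] = (iss - iSp) / tiSp;

    /* ICaL / ICaNa / ICaK */
    const double dss = 1.0 / (1.0 + exp(-(V + 3.940) / 4.230));
    const double td = 0.6 + 1.0 / (exp(-0.05 * (V + 6.0)) + exp(0.09 * (V + 14.0)));
    const double fss = 1.0 / (1.0 + exp((V + 19.58) / 3.696));
    const double tff = 7.0 + 1.0 / (0.0045 * exp(-(V + 20.0) / 10.0)
                                    + 0.0045 * exp((V + 20.0) / 10.0));
    const double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(V + 5.0) / 4.0)
                                       + 0.000035 * exp((V + 5.0) / 6.0));
    const double Aff = 0.6, Afs = 1.0 - Aff;
    const double f = Aff * ff + Afs * fs;
    const double fcass = fss;
    const double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(V - 4.0) / 7.0)
                                      + 0.04 * exp((V - 4.0) / 7.0));
    const double tfcas = 100.0 + 1.0 / (0.00012 * exp(-V / 3.0)
                                        + 0.00012 * exp(V / 7.0));
    const double Afcaf = 0.3 + 0.6 / (1.0 + exp((V - 10.0) / 10.0));
    const double Afcas = 1.0 - Afcaf;
    const double fca = Afcaf * fcaf + Afcas * fcas;
    const double tjca = 75.0;
    const double tffp = 2.5 * tff;
    const double fp = Aff * ffp + Afs * fs;
    const double tfcafp = 2.5 * tfcaf;
    const double fcap = Afcaf * fcafp + Afcas * fcas;
    const double Kmn = 0.002, k2n = 1000.0;
    const double km2n = jca * 1.0;
    const double tmp_nca = 1.0 + Kmn / Cass;
    const double anca = 1.0 / (k2n / km2n
                               + tmp_nca * tmp_nca * tmp_nca * tmp_nca);
    dy[30] = anca * k2n - nca * km2n;
    double e2v = exp(2.0 * vfrt), e1v = exp(vfrt);
    double PhiCaL, PhiCaNa, PhiCaK;
    if (fabs(vfrt) < 1e-7) {
        PhiCaL = 2.0 * Frdy * (Cass * e2v - 0.341 * Cao) / (1.0 + vfrt);
        PhiCaNa = Frdy * (0.75 * Nass * e1v - 0.75 * Nao) / (1.0 + 0.5 * vfrt);
        PhiCaK  = Frdy * (0.75 * Kss * e1v - 0.75 * Ko) / (1.0 + 0.5 * vfrt);
    } else {
        PhiCaL = 4.0 * vffrt * (Cass * e2v - 0.341 * Cao) / (e2v - 1.0);
        PhiCaNa = 1.0 * vffrt * (0.75 * Nass * e1v - 0.75 * Nao) / (e1v - 1.0);
        PhiCaK  = 1.0 * vffrt * (0.75 * Kss * e1v - 0.75 * Ko) / (e1v - 1.0);
    }
    const double PCa = 0.0001 * p[SC_ICAL]; /* endo */
    const double PCap = 1.1 * PCa;
    const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    const double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
    const double gate_p  = d * (fp * (1.0 - nca) + jca * fcap * nca);
    const double ICaL  = (1.0 - fphos) * PCa * PhiCaL * gate_np
                         + fphos * PCap * PhiCaL * gate_p;
    const double ICaNa = (1.0 - fphos) * PCaNa * PhiCaNa * gate_np
                         + fphos * PCaNap * PhiCaNa * gate_p;
    const double ICaK  = (1.0 - fphos) * PCaK * PhiCaK * gate_np
                         + fphos * PCaKp * PhiCaK * gate_p;
    dy[24] = (dss - d) / td;
    dy[25] = (fss - ff) / tff;
    dy[26] = (fss - fs) / tfs;
    dy[27] = (fcass - fcaf) / tfcaf;
    dy[28] = (fcass - fcas) / tfcas;
    dy[29] = (fcass - jca) / tjca;
    dy[31] = (fss - ffp) / tffp;
    dy[32] = (fcass - fcafp) / tfcafp;

    /* IKr */
    const double xrss = 1.0 / (1.0 + exp(-(V + 8.337) / 6.789));
    const double txrf = 12.98 + 1.0 / (0.3652 * exp((V - 31.66) / 3.869)
                                       + 4.123e-5 * exp(-(V - 47.78) / 20.38));
    const double txrs = 1.865 + 1.0 / (0.06629 * exp((V - 34.70) / 7.355)
                                       + 1.128e-5 * exp(-(V - 29.74) / 25.94));
    const double Axrf = 1.0 / (1.0 + exp((V + 54.81) / 38.21));
    const double Axrs = 1.0 - Axrf;
    const double xr = Axrf * xrf + Axrs * xrs;
    const double rkr = 1.0 / ((1.0 + exp((V + 55.0) / 75.0))
                              * (1.0 + exp((V - 10.0) / 30.0)));
    const double GKr = 0.046 * p[SC_IKR]; /* endo */
    const double IKr = GKr * sqrt(Ko / 5.4) * xr * rkr * (V - EK);
    dy[33] = (xrss - xrf) / txrf;
    dy[34] = (xrss - xrs) / txrs;

    /* IKs */
    const double xs1ss = 1.0 / (1.0 + exp(-(V + 11.60) / 8.932));
    const double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((V + 48.28) / 17.80)
                                       + 0.001292 * exp(-(V + 210.0) / 230.0));
    const double xs2ss = xs1ss;
    const double txs2 = 1.0 / (0.01 * exp((V - 50.0) / 20.0)
                               + 0.0193 * exp(-(V + 66.54) / 31.0));
    const double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / Cai, 1.4));
    const double GKs = 0.0034 * p[SC_IKS]; /* endo */
    const double IKs = GKs * KsCa * xs1 * xs2 * (V - EKs);
    dy[35] = (xs1ss - xs1) / txs1;
    dy[36] = (xs2ss - xs2) / txs2;

    /* IK1 */
    const double xk1ss = 1.0 / (1.0 + exp(-(V + 2.5538 * Ko + 144.59)
                                          / (1.5692 * Ko + 3.8115)));
    const double txk1 = 122.2 / (exp(-(V + 127.2) / 20.36)
                                 + exp((V + 236.8) / 69.33));
    const double rk1 = 1.0 / (1.0 + exp((V + 105.8 - 2.6 * Ko) / 9.493));
    const double GK1 = 0.1908 * p[SC_IK1]; /* endo */
    const double IK1 = GK1 * sqrt(Ko) * rk1 * xk1 * (V - EK);
    dy[37] = (xk1ss - xk1) / txk1;

    /* INaCa (sarcolemmal and subspace components) */
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5,
                 wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3,
                 kcaon = 1.5e6, kcaoff = 5.0e3, qna = 0.5224, qca = 0.1670;
    const double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    const double KmCaAct = 150.0e-6;
    const double zna = 1.0, zca = 2.0, zk = 1.0;
    double INaCa_i, INaCa_ss;
    {
        const double h1 = 1.0 + Nai / kna3 * (1.0 + hna);
        const double h2 = (Nai * hna) / (kna3 * h1);
        const double h3 = 1.0 / h1;
        const double h4 = 1.0 + Nai / kna1 * (1.0 + Nai / kna2);
        const double h5 = Nai * Nai / (h4 * kna1 * kna2);
        const double h6 = 1.0 / h4;
        const double h7 = 1.0 + Nao / kna3 * (1.0 + 1.0 / hna);
        const double h8 = Nao / (kna3 * hna * h7);
        const double h9 = 1.0 / h7;
        const double h10 = kasymm + 1.0 + Nao / kna1 * (1.0 + Nao / kna2);
        const double h11 = Nao * Nao / (h10 * kna1 * kna2);
        const double h12 = 1.0 / h10;
        const double k1x = h12 * Cao * kcaon;
        const double k2x = kcaoff;
        const double k3p = h9 * wca, k3pp = h8 * wnaca, k3x = k3p + k3pp;
        const double k4p = h3 * wca / hca, k4pp = h2 * wnaca,
                     k4x = k4p + k4pp;
        const double k5x = kcaoff;
        const double k6x = h6 * Cai * kcaon;
        const double k7x = h5 * h2 * wna;
        const double k8x = h8 * h11 * wna;
        const double x1 = k2x * k4x * (k7x + k6x) + k5x * k7x * (k2x + k3x);
        const double x2 = k1x * k7x * (k4x + k5x) + k4x * k6x * (k1x + k8x);
        const double x3 = k1x * k3x * (k7x + k6x) + k8x * k6x * (k2x + k3x);
        const double x4 = k2x * k8x * (k4x + k5x) + k3x * k5x * (k1x + k8x);
        const double E1 = x1 / (x1 + x2 + x3 + x4);
        const double E2 = x2 / (x1 + x2 + x3 + x4);
        const double E3 = x3 / (x1 + x2 + x3 + x4);
        const double E4 = x4 / (x1 + x2 + x3 + x4);
        const double allo = 1.0 / (1.0 + (KmCaAct / Cai) * (KmCaAct / Cai));
        const double JncxNa = 3.0 * (E4 * k7x - E1 * k8x) + E3 * k4pp
                              - E2 * k3pp;
        const double JncxCa = E2 * k2x - E1 * k1x;
        const double Gncx = 0.0008; /* endo */
        INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }
    {
        const double h1 = 1.0 + Nass / kna3 * (1.0 + hna);
        const double h2 = (Nass * hna) / (kna3 * h1);
        const double h3 = 1.0 / h1;
        const double h4 = 1.0 + Nass / kna1 * (1.0 + Nass / kna2);
        const double h5 = Nass * Nass / (h4 * kna1 * kna2);
        const double h6 = 1.0 / h4;
        const double h7 = 1.0 + Nao / kna3 * (1.0 + 1.0 / hna);
        const double h8 = Nao / (kna3 * hna * h7);
        const double h9 = 1.0 / h7;
        const double h10 = kasymm + 1.0 + Nao / kna1 * (1.0 + Nao / kna2);
        const double h11 = Nao * Nao / (h10 * kna1 * kna2);
        const double h12 = 1.0 / h10;
        const double k1x = h12 * Cao * kcaon;
        const double k2x = kcaoff;
        const double k3p = h9 * wca, k3pp = h8 * wnaca, k3x = k3p + k3pp;
        const double k4p = h3 * wca / hca, k4pp = h2 * wnaca,
                     k4x = k4p + k4pp;
        const double k5x = kcaoff;
        const double k6x = h6 * Cass * kcaon;
        const double k7x = h5 * h2 * wna;
        const double k8x = h8 * h11 * wna;
        const double x1 = k2x * k4x * (k7x + k6x) + k5x * k7x * (k2x + k3x);
        const double x2 = k1x * k7x * (k4x + k5x) + k4x * k6x * (k1x + k8x);
        const double x3 = k1x * k3x * (k7x + k6x) + k8x * k6x * (k2x + k3x);
        const double x4 = k2x * k8x * (k4x + k5x) + k3x * k5x * (k1x + k8x);
        const double E1 = x1 / (x1 + x2 + x3 + x4);
        const double E2 = x2 / (x1 + x2 + x3 + x4);
        const double E3 = x3 / (x1 + x2 + x3 + x4);
        const double E4 = x4 / (x1 + x2 + x3 + x4);
        const double allo = 1.0 / (1.0 + (KmCaAct / Cass) * (KmCaAct / Cass));
        const double JncxNa = 3.0 * (E4 * k7x - E1 * k8x) + E3 * k4pp
                              - E2 * k3pp;
        const double JncxCa = E2 * k2x - E1 * k1x;
        const double Gncx = 0.0008;
        INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }

    /* INaK (Smith-Crampin formulation) */
    double INaK;
    {
        const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4,
                     k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.155;
        const double Knai = Knai0 * exp(delta * vfrt / 3.0);
        const double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
        const double Kki = 0.5, Kko = 0.3582;
        const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
        const double H = 1.0e-7, eP = 4.2, Khp = 1.698e-7,
                     Knap = 224.0, Kxkur = 292.0;
        const double P = eP / (1.0 + H / Khp + Nai / Knap + Ki / Kxkur);
        const double nai_n = Nai / Knai, nao_n = Nao / Knao;
        const double ki_n = Ki / Kki, ko_n = Ko / Kko;
        const double denom_i = (1.0 + nai_n) * (1.0 + nai_n) * (1.0 + nai_n)
                               + (1.0 + ki_n) * (1.0 + ki_n) - 1.0;
        const double denom_o = (1.0 + nao_n) * (1.0 + nao_n) * (1.0 + nao_n)
                               + (1.0 + ko_n) * (1.0 + ko_n) - 1.0;
        const double a1 = k1p * nai_n * nai_n * nai_n / denom_i;
        const double b1 = k1m * MgADP;
        const double a2 = k2p;
        const double b2 = k2m * nao_n * nao_n * nao_n / denom_o;
        const double a3 = k3p * ko_n * ko_n / denom_o;
        const double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
        const double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
        const double b4 = k4m * ki_n * ki_n / denom_i;
        const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3
                          + b3 * a1 * a2;
        const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4
                          + a2 * a3 * b4;
        const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4
                          + a3 * a4 * b1;
        const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1
                          + b3 * b1 * a4;
        const double E1 = x1 / (x1 + x2 + x3 + x4);
        const double E2 = x2 / (x1 + x2 + x3 + x4);
        const double E3 = x3 / (x1 + x2 + x3 + x4);
        const double E4 = x4 / (x1 + x2 + x3 + x4);
        const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        const double Pnak = 30.0; /* endo */
        INaK = Pnak * (zna * JnakNa + zk * JnakK);
    }

    /* background and pump currents */
    const double xkb = 1.0 / (1.0 + exp(-(V - 14.48) / 18.34));
    const double GKb = 0.003;
    const double IKb = GKb * xkb * (V - EK);
    double INab, ICab;
    if (fabs(vfrt) < 1e-7) {
        INab = 3.75e-10 * Frdy * (Nai * e1v - Nao) / (1.0 + 0.5 * vfrt);
        ICab = 2.5e-8 * 2.0 * Frdy * (Cai * e2v - 0.341 * Cao) / (1.0 + vfrt);
    } else {
        INab = 3.75e-10 * vffrt * (Nai * e1v - Nao) / (e1v - 1.0);
        ICab = 2.5e-8 * 4.0 * vffrt * (Cai * e2v - 0.341 * Cao) / (e2v - 1.0);
    }
    const double IpCa = 0.0005 * Cai / (0.0005 + Cai);

    const double Istim = qtsim_stim(t, p);

    /* membrane potential */
    dy[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1
              + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

    /* diffusion fluxes */
    const double JdiffNa = (Nass - Nai) / 2.0;
    const double JdiffK  = (Kss - Ki) / 2.0;
    const double Jdiff   = (Cass - Cai) / 0.2;

    /* SR release */
    const double bt = 4.75;
    const double a_rel = 0.5 * bt;
    const double Jrel_inf = a_rel * (-ICaL)
        / (1.0 + pow(1.5 / Cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / Cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    dy[38] = (Jrel_inf - Jrelnp) / tau_rel;
    const double btp = 1.25 * bt;
    const double a_relp = 0.5 * btp;
    const double Jrel_infp = a_relp * (-ICaL)
        / (1.0 + pow(1.5 / Cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / Cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    dy[39] = (Jrel_infp - Jrelp) / tau_relp;
    const double Jrel = (1.0 - fphos) * Jrelnp + fphos * Jrelp;

    /* SERCA uptake, leak, translocation */
    const double Jupnp = 0.004375 * Cai / (Cai + 0.00092);
    const double Jupp = 2.75 * 0.004375 * Cai / (Cai + 0.00092 - 0.00017);
    const double Jleak = 0.0039375 * Cansr / 15.0;
    const double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
    const double Jtr = (Cansr - Cajsr) / 100.0;

    /* ionic concentrations */
    dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab)
            * Acap / (Frdy * vmyo) + JdiffNa * vss / vmyo;
    dy[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
    dy[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK)
            * Acap / (Frdy * vmyo) + JdiffK * vss / vmyo;
    dy[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
    const double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07,
                 kmtrpn = 0.0005, BSRmax = 0.047, KmBSR = 0.00087,
                 BSLmax = 1.124, KmBSL = 0.0087, csqnmax = 10.0,
                 kmcsqn = 0.8;
    double tmp1 = kmcmdn + Cai, tmp2 = kmtrpn + Cai;
    const double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (tmp1 * tmp1)
                               + trpnmax * kmtrpn / (tmp2 * tmp2));
    dy[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * Frdy * vmyo)
                    - Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    tmp1 = KmBSR + Cass;
    tmp2 = KmBSL + Cass;
    const double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (tmp1 * tmp1)
                                + BSLmax * KmBSL / (tmp2 * tmp2));
    dy[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss)
                     + Jrel * vjsr / vss - Jdiff);
    dy[7] = Jup - Jtr * vjsr / vnsr;
    tmp1 = kmcsqn + Cajsr;
    const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (tmp1 * tmp1));
    dy[8] = Bcajsr * (Jtr - Jrel);
}
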