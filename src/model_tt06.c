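/* ten Tusscher & Panfilov 2006 human ventricular myocyte model,
 * epicardial variant.  19 state variables; voltage in mV, time in ms,
 * intracellular concentrations in mM.
 *
 * State layout:
 *  0 V    1 Ki    2 Nai   3 Cai   4 CaSS  5 CaSR  6 Rprime
 *  7 xr1  8 xr2   9 xs   10 m    11 h    12 j    13 d
 * 14 f   15 f2   16 fCass 17 s   18 r
 */
#include "qtsim.h"

#define Rgas 8314.472
#define Temp 310.0
#define Frdy 96485.3415

void qtsim_rhs_tt06(double t, const double *y, const double *p, double *dy)
{
    const double V = y[0], Ki = y[1], Nai = y[2], Cai = y[3], CaSS = y[4],
                 CaSR = y[5], Rprime = y[6], xr1 = y[7], xr2 = y[8],
                 xs = y[9], m = y[10], h = y[11], j = y[12], d = y[13],
                 f = y[14], f2 = y[15], fCass = y[16], s = y[17], r = y[18];

    const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
    const double Cm = 0.185, Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
    const double RTF = Rgas * Temp / Frdy;

    /* maximal conductances (epicardial), with block scale factors */
    const double GNa  = 14.838   * p[SC_INA];
    const double GK1  = 5.405    * p[SC_IK1];
    const double Gto  = 0.294    * p[SC_ITO];   /* epi */
    const double GKr  = 0.153    * p[SC_IKR];
    const double GKs  = 0.392    * p[SC_IKS];   /* epi */
    const double GCaL = 3.980e-5 * p[SC_ICAL];
    const double GpCa = 0.1238, GpK = 0.0146;
    const double GbNa = 0.00029, GbCa = 0.000592;
    const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
    const double kNaCa = 1000.0, gamma = 0.35, KmCa = 1.38, KmNai = 87.5,
                 ksat = 0.1, alpha_ncx = 2.5;
    const double pKNa = 0.03;

    const double EK  = RTF * log(Ko / Ki);
    const double ENa = RTF * log(Nao / Nai);
    const double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
    const double ECa = 0.5 * RTF * log(Cao / Cai);

    /* INa */
    const double INa = GNa * m * m * m * h * j * (V - ENa);
    double tmp = 1.0 + exp((-56.86 - V) / 9.03);
    const double minf = 1.0 / (tmp * tmp);
    const double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0))
                    + 0.1 / (1.0 + exp((V - 50.0) / 200.0));
    const double taum = am * bm;
    tmp = 1.0 + exp((V + 71.55) / 7.43);
    const double hinf = 1.0 / (tmp * tmp);
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
    const double jinf = hinf;
    const double tauj = 1.0 / (aj + bj);

    /* ICaL (GHK-like driving term around +15 mV offset) */
    const double vf = (V - 15.0) * Frdy / (Rgas * Temp);
    double ICaL;
    if (fabs(vf) < 1e-7) {
        /* series limit: (V-15)/(exp(2 vf)-1) -> RT/(2F (1+vf)) as V -> 15 */
        ICaL = GCaL * d * f * f2 * fCass * 2.0 * Frdy
               * (0.25 * CaSS * exp(2.0 * vf) - Cao) / (1.0 + vf);
    } else {
        ICaL = GCaL * d * f * f2 * fCass * 4.0 * (V - 15.0) * Frdy * Frdy
               / (Rgas * Temp)
               * (0.25 * CaSS * exp(2.0 * vf) - Cao) / (exp(2.0 * vf) - 1.0);
    }
    const double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    const double taud = ad * bd + gd;
    const double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
    const double tauf = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0)
                      + 200.0 / (1.0 + exp((13.0 - V) / 10.0))
                      + 180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    const double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
    const double tauf2 = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0)
                       + 31.0 / (1.0 + exp((25.0 - V) / 10.0))
                       + 80.0 / (1.0 + exp((V + 30.0) / 10.0));
    const double fCassinf = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
    const double taufCass = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;

    /* Ito (epicardial r,s gates) */
    const double Ito = Gto * r * s * (V - EK);
    const double sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    const double taus = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0)
                      + 5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
    const double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    const double taur = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;

    /* IKr */
    const double IKr = GKr * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
    const double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    const double tauxr1 = axr1 * bxr1;
    const double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    const double tauxr2 = axr2 * bxr2;

    /* IKs */
    const double IKs = GKs * xs * xs * (V - EKs);
    const double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    const double tauxs = axs * bxs + 80.0;

    /* IK1 */
    const double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
    const double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0))
                        + exp(0.1 * (V - EK - 10.0)))
                       / (1.0 + exp(-0.5 * (V - EK)));
    const double IK1 = GK1 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

    /* pumps, exchangers, background */
    const double INaK = PNaK * Ko * Nai
        / ((Ko + KmK) * (Nai + KmNa)
           * (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)));
    const double INaCa = kNaCa
        * (exp(gamma * V / RTF) * Nai * Nai * Nai * Cao
           - exp((gamma - 1.0) * V / RTF) * Nao * Nao * Nao * Cai * alpha_ncx)
        / ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao)
           * (1.0 + ksat * exp((gamma - 1.0) * V / RTF)));
    const double IpCa = GpCa * Cai / (Cai + 0.0005);
    const double IpK  = GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
    const double IbNa = GbNa * (V - ENa);
    const double IbCa = GbCa * (V - ECa);

    /* SR calcium handling */
    const double kcasr = 2.5 - 1.5 / (1.0 + (1.5 / CaSR) * (1.5 / CaSR));
    const double k1 = 0.15 / kcasr;
    const double k2 = 0.045 * kcasr;
    const double O = k1 * CaSS * CaSS * Rprime / (0.06 + k1 * CaSS * CaSS);
    const double Irel  = 0.102 * O * (CaSR - CaSS);
    const double Ileak = 0.00036 * (CaSR - Cai);
    const double Iup   = 0.006375 / (1.0 + (0.00025 * 0.00025) / (Cai * Cai));
    const double Ixfer = 0.0038 * (CaSS - Cai);

    const double Istim = qtsim_stim(t, p);

    /* buffering factors */
    tmp = Cai + 0.001;
    const double bufc  = 1.0 / (1.0 + 0.2 * 0.001 / (tmp * tmp));
    tmp = CaSR + 0.3;
    const double bufsr = 1.0 / (1.0 + 10.0 * 0.3 / (tmp * tmp));
    tmp = CaSS + 0.00025;
    const double bufss = 1.0 / (1.0 + 0.4 * 0.00025 / (tmp * tmp));

    dy[0] = -(IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa + INaCa
              + IbCa + IpK + IpCa + Istim);
    dy[1] = -(IK1 + Ito + IKr + IKs + IpK + Istim - 2.0 * INaK)
            * Cm / (Vc * Frdy);
    dy[2] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frdy);
    dy[3] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer
                    - (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frdy));
    dy[4] = bufss * (-ICaL * Cm / (2.0 * Vss * Frdy)
                     + Irel * Vsr / Vss - Ixfer * Vc / Vss);
    dy[5] = bufsr * (Iup - Irel - Ileak);
    dy[6] = -k2 * CaSS * Rprime + 0.005 * (1.0 - Rprime);
    dy[7] = (xr1inf - xr1) / tauxr1;
    dy[8] = (xr2inf - xr2) / tauxr2;
    dy[9] = (xsinf - xs) / tauxs;
    dy[10] = (minf - m) / taum;
    dy[11] = (hinf - h) / tauh;
    dy[12] = (jinf - j) / tauj;
    dy[13] = (dinf - d) / taud;
    dy[14] = (finf - f) / tauf;
    dy[15] = (f2inf - f2) / tauf2;
    dy[16] = (fCassinf - fCass) / taufCass;
    dy[17] = (sinf - s) / taus;
    dy[18] = (rinf - r) / taur;
}
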