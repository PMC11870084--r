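/* Murine ventricular cardiomyocyte ionic model (Bondarenko-type, apex
 * variant) coupled to a four-state ChR2(H134R) photocycle and a cation
 * background leak.  Right-hand side for deSolve's compiled-model
 * interface.
 *
 * Units: time ms, potential mV, current density pA/pF, concentrations uM,
 * volumes uL, capacitance uF/cm2, irradiance uW/mm2.
 */

#include <R.h>
#include <math.h>

/* ---- fixed model constants ------------------------------------------- */

/* geometry / physical */
#define Acap   1.534e-4   /* cm2 */
#define Cmem   1.0        /* uF/cm2 */
#define Vmyo   25.84e-6   /* uL */
#define VJSR   0.12e-6
#define VNSR   2.098e-6
#define Vss    1.485e-9
#define Faraday 96.5      /* C/mmol */
#define Rgas   8.314
#define Temp   298.0

/* external concentrations (uM) */
#define Ko_o   5400.0
#define Nao_o  140000.0
#define Cao_o  1800.0

/* Ca buffering / fluxes */
#define CMDNtot 50.0
#define KmCMDN  0.238
#define CSQNtot 15000.0
#define KmCSQN  800.0
#define LTRPNtot 70.0
#define HTRPNtot 140.0
#define khtrpn_p 0.00237
#define khtrpn_m 3.2e-5
#define kltrpn_p 0.0327
#define kltrpn_m 0.0196
#define v1_ryr  4.5
#define v2_leak 1.74e-5
#define v3_up   0.45
#define Km_up   0.5
#define tau_tr  20.0
#define tau_xfer 8.0
#define ka_p 0.006075
#define ka_m 0.07125
#define kb_p 0.00405
#define kb_m 0.965
#define kc_p 0.009
#define kc_m 0.0008

/* L-type Ca */
#define GCaL 0.1729
#define ECaL 63.0
#define Kpc_max 0.23324
#define Kpc_half 20.0
#define Kpcb 0.0005
#define ICaL_max 7.0

/* exchangers / pumps / background */
#define kNaCa 292.8
#define KmNa  87500.0
#define KmCa  1380.0
#define ksat  0.1
#define eta_ncx 0.35
#define INaK_max 0.88
#define Km_Nai 21000.0
#define Km_Ko  1500.0
#define IpCa_max 1.0
#define Km_pCa 0.5
#define GCab 0.000367
#define GNa  13.0
#define GNab 0.0026

/* K currents (apex parameter set) */
#define GKtof 0.4067
#define GKs   0.00575
#define GKur  0.160
#define GKss  0.050
#define GKr   0.078
#define kf_kr 0.023761
#define kb_kr 0.036778

/* Ca-activated Cl */
#define GClCa 10.0
#define Km_Cl 10.0
#define ECl  -40.0

/* ChR2 photocycle (empirical four-state H134R model) */
#define chr2_eps1 0.8535
#define chr2_eps2 0.14
#define chr2_taup 1.3      /* ms, activation time constant */
#define chr2_Gd2  0.05     /* 1/ms */
/* irradiance E (uW/mm2) -> absorbed-photon rate: kF*E (1/ms) */
#define chr2_kF   2.183e-5
/* irradiance -> normalized photon flux (units of 1e16 photons/s/cm2) */
#define chr2_kphi 0.02365

/* ---- state layout ----------------------------------------------------- */
enum {
  iV = 0, iCai, iCass, iCaJSR, iCaNSR, iLTRPN, iHTRPN,
  iPO1, iPO2, iPC2,
  iOl, iC2l, iC3l, iC4l, iI1l, iI2l, iI3l,
  iPRyR,
  iNai, iKi,
  iCNa2, iCNa1, iONa, iIFNa, iI1Na, iI2Na, iICNa2, iICNa3,
  iatof, iitof, inKs, iaur, iiur, iaKss, iiKss,
  iCK1, iCK2, iOK, iIKr,
  iO1c, iO2c, iC2c, ipc,
  NSTATE
};

/* ---- run-time parameters ---------------------------------------------- */
#define NPAR 17
static double parms[NPAR];
#define s_K1    parms[0]
#define s_NaK   parms[1]
#define s_Nab   parms[2]
#define s_Na    parms[3]
#define p_ir    parms[4]
#define g_leak  parms[5]
#define b_Na    parms[6]   /* remaining-conductance scales (1 = no block) */
#define b_CaL   parms[7]
#define b_Kr    parms[8]
#define b_Ks    parms[9]
#define b_K1    parms[10]
#define b_to    parms[11]
#define b_Kur   parms[12]
#define b_Kss   parms[13]
#define g_chr2  parms[14]
#define gam_chr2 parms[15]
#define irrad   parms[16]

void cell_init(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, parms);
}

void cell_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  const double RTF = Rgas * Temp / Faraday;
  double V = y[iV];
  double Cai = y[iCai], Cass = y[iCass];
  double CaJSR = y[iCaJSR], CaNSR = y[iCaNSR];
  double Nai = y[iNai], Ki = y[iKi];

  /* reversal potentials */
  double ENa = RTF * log((0.9 * Nao_o + 0.1 * Ko_o) /
                         (0.9 * Nai + 0.1 * Ki));
  double EK = RTF * log(Ko_o / Ki);
  double ECaN = 0.5 * RTF * log(Cao_o / Cai);

  /* --- membrane currents (pA/pF) --- */
  double ICaL = b_CaL * GCaL * y[iOl] * (V - ECaL);
  double IpCa = IpCa_max * Cai * Cai / (Km_pCa * Km_pCa + Cai * Cai);
  double VFRT = V / RTF;
  double INaCa = kNaCa / (KmNa * KmNa * KmNa + Nao_o * Nao_o * Nao_o) /
    (KmCa + Cao_o) / (1.0 + ksat * exp((eta_ncx - 1.0) * VFRT)) *
    (exp(eta_ncx * VFRT) * Nai * Nai * Nai * Cao_o -
     exp((eta_ncx - 1.0) * VFRT) * Nao_o * Nao_o * Nao_o * Cai);
  double ICab = GCab * (V - ECaN);
  double INa = s_Na * b_Na * GNa * y[iONa] * (V - ENa);
  double INab = s_Nab * GNab * (V - ENa);
  double sigma = (exp(Nao_o / 67300.0) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * VFRT) +
                       0.0365 * sigma * exp(-VFRT));
  double INaK = s_NaK * INaK_max * fNaK /
    (1.0 + pow(Km_Nai / Nai, 1.5)) * Ko_o / (Ko_o + Km_Ko);
  double Itof = b_to * GKtof * y[iatof] * y[iatof] * y[iatof] *
    y[iitof] * (V - EK);
  double xK1 = V - EK;
  double IK1 = s_K1 * b_K1 * 0.2938 * (Ko_o / (Ko_o + 210.0)) *
    xK1 / (1.0 + exp(p_ir * xK1));
  double IKs = b_Ks * GKs * y[inKs] * y[inKs] * (V - EK);
  double IKur = b_Kur * GKur * y[iaur] * y[iiur] * (V - EK);
  double IKss = b_Kss * GKss * y[iaKss] * y[iiKss] * (V - EK);
  double EKr = RTF * log((0.98 * Ko_o + 0.02 * Nao_o) /
                         (0.98 * Ki + 0.02 * Nai));
  double IKr = b_Kr * GKr * y[iOK] * (V - EKr);
  double OClCa = 0.2 / (1.0 + exp(-(V - 46.7) / 7.8));
  double IClCa = GClCa * OClCa * Cai / (Cai + Km_Cl) * (V - ECl);

  /* cation background leak: Na conductance 1, K conductance 0.5 */
  double Ileak_Na = g_leak * (V - ENa);
  double Ileak_K = -0.5 * g_leak * (V - EK);
  double Ileak = Ileak_Na + Ileak_K;

  /* ChR2 photocurrent: empirical rectification drive, reversal ~+13.6 mV */
  double chr2_drive = 10.6408 - 14.6408 * exp(-V / 42.7671);
  double IChR2 = g_chr2 * chr2_drive * (y[iO1c] + gam_chr2 * y[iO2c]);

  ydot[iV] = -(ICaL + IpCa + INaCa + ICab + INa + INab + INaK + Itof +
               IK1 + IKs + IKur + IKss + IKr + IClCa + Ileak + IChR2);

  /* --- Ca handling --- */
  double Bi = 1.0 / (1.0 + CMDNtot * KmCMDN /
                     ((KmCMDN + Cai) * (KmCMDN + Cai)));
  double Bss = 1.0 / (1.0 + CMDNtot * KmCMDN /
                      ((KmCMDN + Cass) * (KmCMDN + Cass)));
  double BJSR = 1.0 / (1.0 + CSQNtot * KmCSQN /
                       ((KmCSQN + CaJSR) * (KmCSQN + CaJSR)));
  double Jrel = v1_ryr * (y[iPO1] + y[iPO2]) * (CaJSR - Cass) * y[iPRyR];
  double Jtr = (CaNSR - CaJSR) / tau_tr;
  double Jxfer = (Cass - Cai) / tau_xfer;
  double Jleak = v2_leak * (CaNSR - Cai);
  double Jup = v3_up * Cai * Cai / (Km_up * Km_up + Cai * Cai);
  double dLTRPN = kltrpn_p * Cai * (LTRPNtot - y[iLTRPN]) -
    kltrpn_m * y[iLTRPN];
  double dHTRPN = khtrpn_p * Cai * (HTRPNtot - y[iHTRPN]) -
    khtrpn_m * y[iHTRPN];
  double Jtrpn = dLTRPN + dHTRPN;

  ydot[iCai] = Bi * (Jleak + Jxfer - Jup - Jtrpn -
                     (ICab + IpCa - 2.0 * INaCa) * Acap * Cmem /
                     (2.0 * Vmyo * Faraday));
  ydot[iCass] = Bss * (Jrel * VJSR / Vss - Jxfer * Vmyo / Vss -
                       ICaL * Acap * Cmem / (2.0 * Vss * Faraday));
  ydot[iCaJSR] = BJSR * (Jtr - Jrel);
  ydot[iCaNSR] = (Jup - Jleak) * Vmyo / VNSR - Jtr * VJSR / VNSR;
  ydot[iLTRPN] = dLTRPN;
  ydot[iHTRPN] = dHTRPN;
  ydot[iPRyR] = -0.04 * y[iPRyR] -
    0.1 * (ICaL / ICaL_max) * exp(-(V - 5.0) * (V - 5.0) / 648.0);

  /* RyR Markov chain */
  {
    double PC1 = 1.0 - y[iPC2] - y[iPO1] - y[iPO2];
    double ca4 = Cass * Cass * Cass * Cass;
    double ca3 = Cass * Cass * Cass;
    ydot[iPO1] = ka_p * ca4 * PC1 - ka_m * y[iPO1] -
      kb_p * ca3 * y[iPO1] + kb_m * y[iPO2] -
      kc_p * y[iPO1] + kc_m * y[iPC2];
    ydot[iPO2] = kb_p * ca3 * y[iPO1] - kb_m * y[iPO2];
    ydot[iPC2] = kc_p * y[iPO1] - kc_m * y[iPC2];
  }

  /* L-type Ca Markov chain */
  {
    double alpha = 0.4 * exp((V + 12.0) / 10.0) *
      (1.0 + 0.7 * exp(-(V + 40.0) * (V + 40.0) / 10.0) -
       0.75 * exp(-(V + 20.0) * (V + 20.0) / 400.0)) /
      (1.0 + 0.12 * exp((V + 12.0) / 10.0));
    double beta = 0.05 * exp(-(V + 12.0) / 13.0);
    double gamma_l = Kpc_max * Cass / (Kpc_half + Cass);
    double Kpcf = 13.0 * (1.0 - exp(-(V + 14.5) * (V + 14.5) / 100.0));
    double O = y[iOl], C2 = y[iC2l], C3 = y[iC3l], C4 = y[iC4l];
    double I1 = y[iI1l], I2 = y[iI2l], I3 = y[iI3l];
    double C1 = 1.0 - (O + C2 + C3 + C4 + I1 + I2 + I3);
    ydot[iOl] = alpha * C4 - 4.0 * beta * O + Kpcb * I1 - gamma_l * O +
      0.001 * (alpha * I2 - Kpcf * O);
    ydot[iC2l] = 4.0 * alpha * C1 + 2.0 * beta * C3 -
      (beta + 3.0 * alpha) * C2;
    ydot[iC3l] = 3.0 * alpha * C2 + 3.0 * beta * C4 -
      (2.0 * beta + 2.0 * alpha) * C3;
    ydot[iC4l] = 2.0 * alpha * C3 + 4.0 * beta * O -
      (3.0 * beta + alpha) * C4 +
      0.01 * (4.0 * Kpcb * beta * I1 - alpha * gamma_l * C4) +
      0.002 * (4.0 * beta * I2 - Kpcf * C4) +
      4.0 * beta * Kpcb * I3 - gamma_l * Kpcf * C4;
    ydot[iI1l] = gamma_l * O - Kpcb * I1 +
      0.001 * (alpha * I3 - Kpcf * I1) +
      0.01 * (alpha * gamma_l * C4 - 4.0 * beta * Kpcb * I1);
    ydot[iI2l] = 0.001 * (Kpcf * O - alpha * I2) + Kpcb * I3 -
      gamma_l * I2 + 0.002 * (Kpcf * C4 - 4.0 * beta * I2);
    ydot[iI3l] = 0.001 * (Kpcf * I1 - alpha * I3) + gamma_l * I2 -
      Kpcb * I3 + gamma_l * Kpcf * C4 - 4.0 * beta * Kpcb * I3;
  }

  /* fast Na Markov chain */
  {
    double a11 = 3.802 / (0.1027 * exp(-(V + 2.5) / 17.0) +
                          0.20 * exp(-(V + 2.5) / 150.0));
    double a12 = 3.802 / (0.1027 * exp(-(V + 2.5) / 15.0) +
                          0.23 * exp(-(V + 2.5) / 150.0));
    double a13 = 3.802 / (0.1027 * exp(-(V + 2.5) / 12.0) +
                          0.25 * exp(-(V + 2.5) / 150.0));
    double b11 = 0.1917 * exp(-(V + 2.5) / 20.3);
    double b12 = 0.20 * exp(-(V - 2.5) / 20.3);
    double b13 = 0.22 * exp(-(V - 7.5) / 20.3);
    double a3 = 7.0e-7 * exp(-(V + 7.0) / 7.7);
    double b3 = 0.0084 + 0.00002 * (V + 7.0);
    double a2 = 1.0 / (0.188495 * exp(-(V + 7.0) / 16.6) + 0.393956);
    double b2 = a13 * a2 * a3 / (b13 * b3);
    double a4 = a2 / 1000.0, b4 = a3;
    double a5 = a2 / 95000.0, b5 = a3 / 50.0;
    double CNa2 = y[iCNa2], CNa1 = y[iCNa1], ONa = y[iONa];
    double IFNa = y[iIFNa], I1Na = y[iI1Na], I2Na = y[iI2Na];
    double ICNa2 = y[iICNa2], ICNa3 = y[iICNa3];
    double CNa3 = 1.0 - (CNa2 + CNa1 + ONa + IFNa + I1Na + I2Na +
                         ICNa2 + ICNa3);
    ydot[iCNa2] = a11 * CNa3 + b12 * CNa1 + a3 * ICNa2 -
      (b11 + a12 + b3) * CNa2;
    ydot[iCNa1] = a12 * CNa2 + b13 * ONa + a3 * IFNa -
      (b12 + a13 + b3) * CNa1;
    ydot[iONa] = a13 * CNa1 + b2 * IFNa - (b13 + a2) * ONa;
    ydot[iIFNa] = a2 * ONa + b3 * CNa1 + b4 * I1Na + a12 * ICNa2 -
      (b2 + a3 + a4 + b12) * IFNa;
    ydot[iI1Na] = a4 * IFNa + b5 * I2Na - (b4 + a5) * I1Na;
    ydot[iI2Na] = a5 * I1Na - b5 * I2Na;
    ydot[iICNa2] = a11 * ICNa3 + b12 * IFNa + b3 * CNa2 -
      (b11 + a12 + a3) * ICNa2;
    ydot[iICNa3] = b11 * ICNa2 + b3 * CNa3 - (a11 + a3) * ICNa3;
  }

  /* Ito,f gating */
  {
    double aa = 0.18064 * exp(0.03577 * (V + 30.0));
    double ba = 0.3956 * exp(-0.06237 * (V + 30.0));
    double ai = 0.000152 * exp(-(V + 13.5) / 7.0) /
      (0.0067083 * exp(-(V + 33.5) / 7.0) + 1.0);
    double bi = 0.00095 * exp((V + 33.5) / 7.0) /
      (0.051335 * exp((V + 33.5) / 7.0) + 1.0);
    ydot[iatof] = aa * (1.0 - y[iatof]) - ba * y[iatof];
    ydot[iitof] = ai * (1.0 - y[iitof]) - bi * y[iitof];
  }

  /* IKs gating (guard the removable singularity at V = -26.5) */
  {
    double u = V + 26.5;
    double an = (fabs(u) < 1e-6) ?
      4.81333e-6 / 0.128 :
      4.81333e-6 * u / (1.0 - exp(-0.128 * u));
    double bn = 9.53333e-5 * exp(-0.038 * u);
    ydot[inKs] = an * (1.0 - y[inKs]) - bn * y[inKs];
  }

  /* IKur and IKss gating */
  {
    double ass = 1.0 / (1.0 + exp(-(V + 22.5) / 7.7));
    double iss = 1.0 / (1.0 + exp((V + 45.2) / 5.7));
    double ta = 0.493 * exp(-0.0629 * V) + 2.058;
    double ti = 1200.0 - 170.0 / (1.0 + exp((V + 45.2) / 5.7));
    double tss = 39.3 * exp(-0.0862 * V) + 13.17;
    ydot[iaur] = (ass - y[iaur]) / ta;
    ydot[iiur] = (iss - y[iiur]) / ti;
    ydot[iaKss] = (ass - y[iaKss]) / tss;
    ydot[iiKss] = 0.0;
  }

  /* IKr Markov chain */
  {
    double a0 = 0.022348 * exp(0.01176 * V);
    double b0 = 0.047002 * exp(-0.0631 * V);
    double a1 = 0.013733 * exp(0.038198 * V);
    double b1 = 6.89e-5 * exp(-0.04178 * V);
    double akr = 0.090821 * exp(0.023391 * (V + 5.0));
    double bkr = 0.006497 * exp(-0.03268 * (V + 5.0));
    double CK0 = 1.0 - (y[iCK1] + y[iCK2] + y[iOK] + y[iIKr]);
    ydot[iCK1] = a0 * CK0 - b0 * y[iCK1] + kb_kr * y[iCK2] -
      kf_kr * y[iCK1];
    ydot[iCK2] = kf_kr * y[iCK1] - kb_kr * y[iCK2] + b1 * y[iOK] -
      a1 * y[iCK2];
    ydot[iOK] = a1 * y[iCK2] - b1 * y[iOK] + bkr * y[iIKr] -
      akr * y[iOK];
    ydot[iIKr] = akr * y[iOK] - bkr * y[iIKr];
  }

  /* intracellular ion concentrations; ChR2 flux booked as Na+ */
  ydot[iNai] = -(INa + INab + 3.0 * INaK + 3.0 * INaCa + Ileak_Na +
                 IChR2) * Acap * Cmem / (Vmyo * Faraday);
  ydot[iKi] = -(Itof + IK1 + IKs + IKss + IKur + IKr - 2.0 * INaK +
                Ileak_K) * Acap * Cmem / (Vmyo * Faraday);

  /* --- ChR2 photocycle --- */
  {
    double E = irrad;
    double phiu = chr2_kphi * E; /* 1e16 photons/s/cm2 */
    double e12 = 0.011 + 0.005 * log(1.0 + phiu / 0.024);
    double e21 = 0.008 + 0.004 * log(1.0 + phiu / 0.004);
    double S0 = 0.5 * (1.0 + tanh(120.0 * (phiu - 0.1)));
    double Gd1 = 0.075 + 0.043 * tanh(-(V + 20.0) / 20.0);
    double Gr = 4.34587e-5 * exp(-0.0211539274 * V);
    double k1 = chr2_eps1 * chr2_kF * E * y[ipc];
    double k2 = chr2_eps2 * chr2_kF * E * y[ipc];
    double O1 = y[iO1c], O2 = y[iO2c], C2 = y[iC2c];
    double C1 = 1.0 - O1 - O2 - C2;
    ydot[iO1c] = k1 * C1 - (Gd1 + e12) * O1 + e21 * O2;
    ydot[iO2c] = k2 * C2 + e12 * O1 - (chr2_Gd2 + e21) * O2;
    ydot[iC2c] = chr2_Gd2 * O2 - (k2 + Gr) * C2;
    ydot[ipc] = (S0 - y[ipc]) / chr2_taup;
  }

  if (ip[0] >= 2) {
    yout[0] = IChR2;
    yout[1] = IK1;
  }
}
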