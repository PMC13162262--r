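"""Independent seawater CO2-system oracle.

Total pH scale; Lueker et al. (2000) K1/K2; Dickson (1990) KB and KSO4;
Perez & Fraga (1987) KF; Millero (1995) KW (SWS, converted); Lee et al.
(2010) total boron.  Constants transcribed directly from the literature,
independently of the R package.  Used only to freeze reference values
into test fixtures.
"""
import numpy as np
from scipy.optimize import brentq


def totals(S):
    TB = 0.0004326 * S / 35.0                    # Lee et al. 2010, mol/kg
    TS = (0.14 / 96.062) * (S / 1.80655)         # Morris & Riley 1966
    TF = (0.000067 / 18.998) * (S / 1.80655)     # Riley 1965
    return TB, TS, TF


def constants(tC, S):
    T = tC + 273.15
    lnT = np.log(T)
    pK1 = 3633.86 / T - 61.2172 + 9.6777 * lnT - 0.011555 * S + 0.0001152 * S**2
    pK2 = 471.78 / T + 25.929 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S**2
    K1, K2 = 10.0**-pK1, 10.0**-pK2
    lnKB = ((-8966.90 - 2890.53 * S**0.5 - 77.942 * S + 1.728 * S**1.5
             - 0.0996 * S**2) / T
            + 148.0248 + 137.1942 * S**0.5 + 1.62142 * S
            + (-24.4344 - 25.085 * S**0.5 - 0.2474 * S) * lnT
            + 0.053105 * S**0.5 * T)
    KB = np.exp(lnKB)
    IonS = 19.924 * S / (1000.0 - 1.005 * S)
    lnKS = (-4276.1 / T + 141.328 - 23.093 * lnT
            + (-13856.0 / T + 324.57 - 47.986 * lnT) * IonS**0.5
            + (35474.0 / T - 771.54 + 114.723 * lnT) * IonS
            - 2698.0 / T * IonS**1.5 + 1776.0 / T * IonS**2
            + np.log(1.0 - 0.001005 * S))
    KS = np.exp(lnKS)                            # free scale
    KF = np.exp(874.0 / T - 9.68 + 0.111 * S**0.5)   # total scale
    lnKW = (148.9802 - 13847.26 / T - 23.6521 * lnT
            + (118.67 / T - 5.977 + 1.0495 * lnT) * S**0.5 - 0.01615 * S)
    TB, TS, TF = totals(S)
    SWStoTOT = (1.0 + TS / KS) / (1.0 + TS / KS + TF / KF)
    KW = np.exp(lnKW) * SWStoTOT                 # SWS -> total
    return dict(K1=K1, K2=K2, KB=KB, KW=KW, KS=KS, KF=KF, TB=TB, TS=TS, TF=TF)


def alk_from_ph(pH, DIC, k):
    """DIC in mol/kg; returns TA mol/kg."""
    H = 10.0**-pH
    Hfree = H / (1.0 + k['TS'] / k['KS'])
    den = H * H + k['K1'] * H + k['K1'] * k['K2']
    HCO3 = DIC * k['K1'] * H / den
    CO3 = DIC * k['K1'] * k['K2'] / den
    BOH4 = k['TB'] * k['KB'] / (k['KB'] + H)
    OH = k['KW'] / H
    HSO4 = k['TS'] * Hfree / (k['KS'] + Hfree)
    HF = k['TF'] * H / (k['KF'] + H)
    return HCO3 + 2 * CO3 + BOH4 + OH - Hfree - HSO4 - HF


def dic_from_ph(pH, TA, k):
    H = 10.0**-pH
    Hfree = H / (1.0 + k['TS'] / k['KS'])
    BOH4 = k['TB'] * k['KB'] / (k['KB'] + H)
    OH = k['KW'] / H
    HSO4 = k['TS'] * Hfree / (k['KS'] + Hfree)
    HF = k['TF'] * H / (k['KF'] + H)
    CA = TA - BOH4 - OH + Hfree + HSO4 + HF
    den = H * H + k['K1'] * H + k['K1'] * k['K2']
    return CA * den / (k['K1'] * H + 2.0 * k['K1'] * k['K2'])


def ph_from_dic(TA, DIC, k):
    return brentq(lambda p: alk_from_ph(p, DIC, k) - TA, 2.0, 12.0,
                  xtol=1e-12)


def dh_ddic(TA_u, pH, tC, S, step=0.01):
    """umol-based finite difference, mol H+ per mol DIC."""
    k = constants(tC, S)
    TA = TA_u * 1e-6
    DIC = dic_from_ph(pH, TA, k)
    d = step * 1e-6
    Hp = 10.0**-ph_from_dic(TA, DIC + d, k)
    Hm = 10.0**-ph_from_dic(TA, DIC - d, k)
    return (Hp - Hm) / (2 * d)


def dh_ddic2alk(TA_u, pH, tC, S, step=0.01):
    """Calcification stoichiometry: -1 DIC, -2 TA per mol CaCO3."""
    k = constants(tC, S)
    TA = TA_u * 1e-6
    DIC = dic_from_ph(pH, TA, k)
    d = step * 1e-6
    Hp = 10.0**-ph_from_dic(TA - 2 * d, DIC - d, k)
    Hm = 10.0**-ph_from_dic(TA + 2 * d, DIC + d, k)
    return (Hp - Hm) / (2 * d)


if __name__ == '__main__':
    import itertools, sys
    rows = []
    for tC, S, pH, TA in itertools.product([15, 25], [35, 38],
                                           [7.7, 8.0, 8.1], [2300, 2650]):
        k = constants(tC, S)
        dic = dic_from_ph(pH, TA * 1e-6, k) * 1e6
        r1 = dh_ddic(TA, pH, tC, S)
        r2 = dh_ddic2alk(TA, pH, tC, S)
        rows.append((tC, S, pH, TA, dic, r1, r2))
    print("temperature,salinity,ph,alkalinity,dic,dh_ddic,dh_ddic2alk")
    for r in rows:
        print("%g,%g,%g,%g,%.6f,%.8e,%.8e" % r)
    # anchors from study conditions
    k = constants(25, 38)
    d1 = dic_from_ph(8.04, 2650e-6, k) * 1e6
    d2 = dic_from_ph(7.94, 2650e-6, k) * 1e6
    print("# DIC(pH 8.04)=%.3f DIC(pH 7.94)=%.3f dDIC=%.3f" % (d1, d2, d2 - d1),
          file=sys.stderr)
    ph2 = ph_from_dic(2650e-6 - 58.54e-6, d1 * 1e-6 - 29.27e-6, k)
    print("# pH after removing 30 mmol CaCO3 in 1 m3: %.5f (d=%.5f)" %
          (ph2, ph2 - 8.04), file=sys.stderr)
    for tC, S in [(25, 35), (25, 38), (15, 35)]:
        k = constants(tC, S)
        print("# T=%g S=%g pK1=%.5f pK2=%.5f KB=%.4e KW=%.4e KS=%.4e KF=%.4e TB=%.5e"
              % (tC, S, -np.log10(k['K1']), -np.log10(k['K2']), k['KB'],
                 k['KW'], k['KS'], k['KF'], k['TB']), file=sys.stderr)
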