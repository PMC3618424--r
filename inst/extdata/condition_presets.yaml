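# Ground-truth relative permeability presets, normalized to the residual
# P_K of SLO3-mutant non-capacitated sperm at pH 7.4 (assigned 1.0).
# Values restated in the study's running text; entries marked `chosen`
# are this package's documented choices where only a qualitative statement
# exists (see the methods vignette).
#
# pH 8 entries pair P_Na 0.15 -> 0.12 for the mutant as printed in that
# section; elsewhere P_Na = 0.13. The two are deliberately not reconciled.
normalization: SLO3-mutant / non-capacitated / pH 7.4 / P_K = 1.0
base:
  wild-type:
    non-capacitated:
      "7":   {P_K: 1.6,  P_Na: 0.13, P_Cl: 0.6}
      "7.4": {P_K: 1.6,  P_Na: 0.13, P_Cl: 0.6}
      "8":   {P_K: 8.2,  P_Na: 0.13, P_Cl: 0.6}
    capacitated:
      "7":   {P_K: 2.4,  P_Na: 0.13, P_Cl: 0.6, chosen: true}
      "7.4": {P_K: 4.38, P_Na: 0.13, P_Cl: 0.6}
      "8":   {P_K: 8.2,  P_Na: 0.13, P_Cl: 0.6}
  SLO3-mutant:
    non-capacitated:
      "7":   {P_K: 1.0,  P_Na: 0.13, P_Cl: 0.6}
      "7.4": {P_K: 1.0,  P_Na: 0.13, P_Cl: 0.6}
      "8":   {P_K: 1.2,  P_Na: 0.12, P_Cl: 0.6}
    capacitated:
      "7":   {P_K: 1.1,  P_Na: 0.13, P_Cl: 0.6, chosen: true}
      "7.4": {P_K: 1.1,  P_Na: 0.13, P_Cl: 0.6, chosen: true}
      "8":   {P_K: 1.2,  P_Na: 0.12, P_Cl: 0.6}
blockers:
  # amiloride blocks the epithelial-type Na+ channel: P_Na / 6.5
  amiloride: {P_Na_factor: 0.153846153846154}
  # Ba2+ / clofilium remove the SLO3 component of P_K: wild-type P_K is
  # replaced by the SLO3-mutant value for the same state and pH
  Ba:        {remove_slo3: true}
  clofilium: {remove_slo3: true}
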