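# Synthetic omalizumab-IgE QE TMDD parameter set.
#
# Not the published estimates: a calibrated stand-in. ka, F, V, CL_OMA and
# CL_IGE are literature-plausible values for a ~70 kg adult; CL_COMP and KD
# were calibrated once so the model reproduces three published summary
# characteristics of the system: baseline total IgE 422.82 ng/mL, terminal
# total-drug half-life 18.2 days, and a 277.5 mg SC dose giving a 95%
# reduction of free IgE at day 14. IIV (30% CV on the three clearances) and
# proportional residual error (15% CV per analyte) are assumed values.
#
# Units: ka 1/day; V litres; clearances L/day; KD nM; R0 ng/mL; alpha
# dimensionless; omega2 log-scale variances; sigma2 proportional variances;
# mw g/mol.
theta:
  ka: 0.3144
  F: 0.62
  V: 5.9
  CL_OMA: 0.24
  CL_IGE: 1.7
  CL_COMP: 0.2136
  KD: 1.6163
  R0: 422.82
  alpha: 1.0
omega2:
  CL_OMA: 0.09
  CL_IGE: 0.09
  CL_COMP: 0.09
sigma2:
  OMA_TOT: 0.0225
  IGE_FREE: 0.0225
  IGE_TOT: 0.0225
fixed:
- F
mw:
  oma: 149000.0
  ige: 190000.0
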