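# Default synthetic PD population for virtual-patient sampling.
#
# Units: amounts mg, volumes L, concentrations mg/L, time minutes.
# Values are representative of published oral levodopa PK/PD ranges:
# absorption half-life ~25 min, distribution volumes around 11 L (central)
# and 27 L (peripheral), clearance ~31 L/h, effect-compartment
# equilibration half-life ~17 min, baseline TRS near -2 (clear parkinsonian
# symptoms unmedicated) with a maximum effect span keeping BASE + EMAX
# inside the TRS ceiling of 3.
#
# The covariance is reconstructed as D %*% corr %*% D with D = diag(sd).
means:
  ka: 0.028
  BIO: 0.85
  Q: 0.58
  V1: 11.0
  V2: 27.0
  CL: 0.52
  Rsyn: 0.15
  kEO: 0.04
  BASE: -2.0
  EMAX: 4.3
  EC50: 1.5
  gamma: 2.2
sd:
  ka: 0.003
  BIO: 0.04
  Q: 0.06
  V1: 1.3
  V2: 3.2
  CL: 0.05
  Rsyn: 0.022
  kEO: 0.005
  BASE: 0.15
  EMAX: 0.2
  EC50: 0.18
  gamma: 0.15
correlations:
  - pair: [V1, V2]
    value: 0.5
  - pair: [Q, CL]
    value: 0.3
  - pair: [CL, V1]
    value: 0.3
clip_lower:
  ka: 0.008
  BIO: 0.35
  Q: 0.15
  V1: 4.0
  V2: 9.0
  CL: 0.15
  Rsyn: 0.0
  kEO: 0.008
  BASE: -3.0
  EMAX: 1.5
  EC50: 0.4
  gamma: 1.2
clip_upper:
  ka: 0.09
  BIO: 1.0
  Q: 1.6
  V1: 26.0
  V2: 70.0
  CL: 1.3
  Rsyn: 0.5
  kEO: 0.15
  BASE: -0.8
  EMAX: 6.0
  EC50: 3.6
  gamma: 4.0
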