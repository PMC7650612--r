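# Ground-truth configuration of the reduced ErbB fixture model (version 1).
# Chosen once so that all cascade tiers activate appreciably at 10 nM ligand
# and a high-ErbB3/low-ErbB1 line shows transient (EGF) vs sustained (HRG)
# ERK phosphorylation: fast EGF-receptor kinetics give an early pERK peak
# that DUSP feedback then suppresses, while slow HRG-receptor accumulation
# keeps pERK near its (late) peak through the 120-min window.
# Units: time min, ligands nM, amounts arbitrary (TPM-scaled) units.
kinetics:
  ka1: 0.05      # /nM/min  EGF binding-activation of R1 (fast)
  ki1: 0.25      # /min     R1 deactivation
  ka3: 0.002     # /nM/min  HRG binding-activation of R3 (slow)
  ki3: 0.008     # /min     R3 deactivation
  kx: 0.001      # /au/min  receptor-driven Ras-node activation
  kdx: 0.15      # /min     Ras-node deactivation (basal)
  kfb: 0.01      # /au      ERK negative feedback on Ras node
  kmek: 0.002    # /au/min  MEK phosphorylation by Ras node
  kdmek: 0.4     # /min     MEK dephosphorylation
  kerk: 0.008    # /au/min  ERK phosphorylation by MEK
  kderk: 0.15    # /min     ERK dephosphorylation (basal)
  kd: 0.6        # /au      DUSP enhancement of ERK dephosphorylation
  kakt: 0.002    # /au/min  Akt phosphorylation by receptors
  kdakt: 0.1     # /min     Akt dephosphorylation
  ksm: 2.0       # au/min   max c-Fos mRNA synthesis
  K: 40.0        # au       Hill constant of ERK on c-Fos transcription
  "n": 2.0       # -        Hill coefficient (structural, not searched)
  kdm: 0.05      # /min     c-Fos mRNA decay
  ksf: 0.2       # /min     c-Fos translation
  kdf: 0.02      # /min     c-Fos protein decay
  kpf: 0.003     # /au/min  c-Fos phosphorylation by ERK
  kdpf: 0.05     # /min     pc-Fos dephosphorylation
  ksd: 0.03      # /min     DUSP induction by ERK
  kdd: 0.02      # /min     DUSP decay
weights:
  R1: 0.6
  R3: 0.8
  X: 1.2
  MEK: 0.5
  ERK: 0.4
  Akt: 0.3
gene_families:
  R1: [EGFR]
  R3: [ERBB3]
  X: [HRAS, KRAS]
  MEK: [MAP2K1, MAP2K2]
  ERK: [MAPK1, MAPK3]
  Akt: [AKT1, AKT2, AKT3]
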