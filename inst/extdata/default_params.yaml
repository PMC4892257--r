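# Default parameter set for the coupled Notch-Delta-Jagged / EMT circuit.
# Units: abundances in molecules, production rates g_* in molecules/h,
# degradation rates gamma_* in 1/h, binding rates kc/kt in 1/(molecules h).
# Shifted-Hill edges: X0 (molecules), n (Hill coefficient), lambda (fold
# change at saturation; < 1 represses, > 1 activates).
# MicroRNA records: mu0 (molecules), per-occupancy translation factors and
# (for explicit mRNAs) active mRNA degradation / microRNA consumption rates.

notch:
  gN: 80.0         # Notch receptor production
  gD: 2000.0       # Delta production (one-cell default; tissue runs override)
  gJ: 200.0        # Jagged production (one-cell default; tissue runs override)
  kc: 2.0e-4       # cis-inhibition rate
  kt: 5.0e-5       # trans-activation rate
  affinityD: 0.8   # baseline Notch-Delta trans affinity (unglycosylated receptor)
  affinityJ: 1.0   # baseline Notch-Jagged trans affinity
  gammaN: 0.1
  gammaD: 0.1
  gammaJ: 0.1
  gammaI: 0.5      # NICD degradation
  hill_I_N:        # NICD activates Notch transcription
    X0: 15.0
    "n": 4
    lambda: 3.0
  hill_I_D:        # NICD represses Delta
    X0: 28.0
    "n": 6
    lambda: 0.0
  hill_I_J:        # NICD activates Jagged
    X0: 15.0
    "n": 4
    lambda: 2.0
  mir34_N:         # miR-34 translationally inhibits Notch (2 sites)
    mu0: 10000.0
    translation: [1.0, 0.7, 0.5]
  mir34_D:         # miR-34 translationally inhibits Delta (2 sites)
    mu0: 10000.0
    translation: [1.0, 0.6, 0.3]
  mir200_J:        # miR-200 translationally inhibits Jagged (3 sites)
    mu0: 10000.0
    translation: [1.0, 0.6, 0.3, 0.1]

emt:
  # The EMT-core kinetic scale (all six production and six degradation
  # rates, and the microRNA-machinery rates below) is half the canonical
  # fast scale; this leaves every steady state and bifurcation unchanged
  # and sets the relaxation clock of partial-EMT transients.
  gu34: 675.0      # miR-34 production
  gms: 45.0        # SNAIL mRNA production
  gs: 50.0         # SNAIL translation (per mRNA)
  gu200: 1050.0    # miR-200 production
  gmz: 5.5         # ZEB mRNA production
  gz: 50.0         # ZEB translation (per mRNA)
  gammau34: 0.025
  gammams: 0.25
  gammas: 0.0625
  gammau200: 0.025
  gammamz: 0.25
  gammaz: 0.05
  hill_Z_u200:     # ZEB represses miR-200
    X0: 220000.0
    "n": 3
    lambda: 0.1
  hill_S_u200:     # SNAIL represses miR-200
    X0: 180000.0
    "n": 2
    lambda: 0.1
  hill_Z_mz:       # ZEB self-activation
    X0: 25000.0
    "n": 2
    lambda: 7.5
  hill_S_mz:       # SNAIL activates ZEB
    X0: 180000.0
    "n": 2
    lambda: 10.0
  hill_S_u34:      # SNAIL represses miR-34
    X0: 300000.0
    "n": 1
    lambda: 0.1
  hill_Z_u34:      # ZEB represses miR-34
    X0: 600000.0
    "n": 1
    lambda: 0.2
  hill_S_ms:       # SNAIL self-inhibition
    X0: 200000.0
    "n": 1
    lambda: 0.1
  mir34_ms:        # miR-34 on SNAIL mRNA (2 sites, full machinery)
    mu0: 10000.0
    translation: [1.0, 0.6, 0.3]
    mrna_deg: [0.0, 0.02, 0.1]
    mirna_deg: [0.0, 0.0025, 0.025]
  mir200_mz:       # miR-200 on ZEB mRNA (6 sites, full machinery)
    mu0: 10000.0
    translation: [1.0, 0.6, 0.3, 0.1, 0.05, 0.05, 0.05]
    mrna_deg: [0.0, 0.02, 0.1, 0.5, 0.5, 0.5, 0.5]
    mirna_deg: [0.0, 0.0025, 0.025, 0.25, 0.25, 0.25, 0.25]

coupling:
  hill_I_ms:       # NICD activates SNAIL transcription
    X0: 75.0
    "n": 2
    lambda: 8.0
  hill_Iext_ms:    # external EMT-inducing signal activates SNAIL
    X0: 50.0
    "n": 2
    lambda: 10.0

fringe:
  enabled: false
  gF: 30.0         # Fringe production (NICD-activated)
  gammaF: 0.1
  hill_I_F:
    X0: 150.0
    "n": 2
    lambda: 4.0
  hill_F_delta:    # scales Notch-Delta binding up
    X0: 300.0
    "n": 2
    lambda: 3.0
  hill_F_jagged:   # scales Notch-Jagged binding down
    X0: 300.0
    "n": 2
    lambda: 0.3

phenotype:
  # miR-200 band boundaries separating M / EM / E, and per-species
  # "high" boundaries for the Sender/Receiver classifier. Derived from the
  # model itself (see derive_thresholds()); overridable here.
  mir200_lower: 3886.0
  mir200_upper: 14830.0
  notch_high: 232.0
  delta_high: 463.0
  jagged_high: 318.0
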