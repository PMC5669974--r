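# Default 21-node EGFR/IGF1R - MAPK - PI3K/mTOR signaling model.
#
# Construction rules (see the methods vignette):
#   - every enzymatic edge follows Michaelis-Menten kinetics on the substrate
#     fraction; basal (de)activation is mass action
#   - each node obeys the conservation law active + inactive = 1, so only the
#     active fraction is integrated
#   - receptors are driven by a constant extracellular stimulus level
#   - RasGAP, RafPP and PP2A are constitutive phosphatases clamped at a
#     constant active fraction (a sampled parameter, no dynamics)
#   - CASP represents cleaved effector caspase: cleavage is irreversible, so
#     it carries no basal deactivation
# Parameter count: 30 k + 30 K + 17 kdec + 4 stim + 3 level + 2 kact = 86.
name: egfr_igf1r_mapk_pi3k_mtor
horizon: 100
receptor_seed: 0.001
nominal:
  k: 1.0
  K: 0.5
  kdec: 0.2
  stim: 0.5
  kact: 0.5
  level: 0.5
nodes:
  - {name: EGFR,   role: input-receptor}
  - {name: IGF1R,  role: input-receptor}
  - {name: ERBB4,  role: input-receptor}
  - {name: cKIT,   role: input-receptor}
  - {name: SOS,    role: kinase}
  - {name: RAS,    role: kinase}
  - {name: RasGAP, role: phosphatase, clamped: true}
  - {name: RAF,    role: kinase}
  - {name: RafPP,  role: phosphatase, clamped: true}
  - {name: MEK,    role: kinase}
  - {name: ERK,    role: kinase}
  - {name: p90RSK, role: kinase}
  - {name: PP2A,   role: phosphatase, clamped: true}
  - {name: PI3K,   role: kinase}
  - {name: AKT,    role: kinase}
  - {name: mTOR,   role: kinase}
  - {name: p70S6K, role: kinase}
  - {name: AMPK,   role: kinase}
  - {name: LKB1,   role: kinase, basal_activation: true}
  - {name: BAD,    role: effector, basal_activation: true}
  - {name: CASP,   role: effector, irreversible: true}
edges:
  - {source: EGFR,   target: SOS,    sign: activating}
  - {source: IGF1R,  target: SOS,    sign: activating}
  - {source: ERBB4,  target: SOS,    sign: activating}
  - {source: cKIT,   target: SOS,    sign: activating}
  - {source: EGFR,   target: PI3K,   sign: activating}
  - {source: IGF1R,  target: PI3K,   sign: activating}
  - {source: ERBB4,  target: PI3K,   sign: activating}
  - {source: cKIT,   target: PI3K,   sign: activating}
  - {source: SOS,    target: RAS,    sign: activating}
  - {source: RasGAP, target: RAS,    sign: inhibiting}
  - {source: RAS,    target: RAF,    sign: activating}
  - {source: RafPP,  target: RAF,    sign: inhibiting}
  - {source: AKT,    target: RAF,    sign: inhibiting}
  - {source: RAF,    target: MEK,    sign: activating}
  - {source: MEK,    target: ERK,    sign: activating}
  - {source: PP2A,   target: MEK,    sign: inhibiting}
  - {source: PP2A,   target: ERK,    sign: inhibiting}
  - {source: ERK,    target: p90RSK, sign: activating}
  - {source: p90RSK, target: SOS,    sign: inhibiting}
  - {source: p90RSK, target: BAD,    sign: inhibiting}
  - {source: PI3K,   target: AKT,    sign: activating}
  - {source: AKT,    target: mTOR,   sign: activating}
  - {source: AKT,    target: BAD,    sign: inhibiting}
  - {source: AKT,    target: CASP,   sign: inhibiting}
  - {source: LKB1,   target: AMPK,   sign: activating}
  - {source: ERK,    target: LKB1,   sign: inhibiting}
  - {source: AMPK,   target: mTOR,   sign: inhibiting}
  - {source: mTOR,   target: p70S6K, sign: activating}
  - {source: p70S6K, target: PI3K,   sign: inhibiting}
  - {source: BAD,    target: CASP,   sign: activating}
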