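# Synthetic reference parameterization of the five-component TNF death
# circuit (activated TRADD, phosphorylated RIP1, phosphorylated RIP3,
# TRADD-activated caspase-8 C8a, RIP1-activated caspase-8 C8b).
#
# These values are NOT a transcription of an experimentally fitted table:
# they were calibrated so the deterministic model reproduces the published
# qualitative and quantitative behavior of this circuit (biphasic/emergent
# RIP1-dependent pRIP3 response with emergence near 10% RIP1, coexistence of
# the apoptotic and necroptotic attractors at intermediate RIP1, loss of
# biphasic-emergent dynamics only under k5/k7/k9 removal, loss of
# coexistence under k3 removal, and the reported landmarks of the biphasic
# scale H). See the methods vignette for the calibration protocol.
#
# Term labels among RIP1/RIP3/C8b:
#   k1 C8b -| RIP1    k2 RIP1 self-act   k3 RIP3 -> RIP1
#   k4 C8b self-act   k5 RIP1 -> C8b     k6 RIP3 -| C8b
#   k7 RIP1 -> RIP3   k8 RIP3 self-act   k9 C8b -| RIP3
nodes:
- name: TRADD
  total: 1.0
  d: 0.10763
  basal: 0.0
- name: RIP1
  total: 1.0
  d: 0.10763
  basal: 0.0
- name: RIP3
  total: 1.0
  d: 0.182089
  basal: 0.0
- name: C8a
  total: 1.0
  d: 0.10763
  basal: 0.0
- name: C8b
  total: 1.0
  d: 0.10763
  basal: 0.0
edges:
- {source: .stim, target: TRADD, sign: 1, k: 1, j: 0.25, "n": 2}
- {source: .stim, target: RIP1, sign: 1, k: 0.0511537, j: 0.542669, "n": 2}
- {source: TRADD, target: RIP1, sign: -1, k: 0.425202, j: 0.09, "n": 2}
- {source: RIP1, target: TRADD, sign: -1, k: 12.9885, j: 0.0625, "n": 2}
- {source: TRADD, target: C8a, sign: 1, k: 1, j: 0.09, "n": 2}
- {source: C8b, target: RIP1, sign: -1, k: 0.65701, j: 0.09, "n": 2}   # k1
- {source: RIP1, target: RIP1, sign: 1, k: 0.430525, j: 0.09, "n": 2}   # k2
- {source: RIP3, target: RIP1, sign: 1, k: 7.02818, j: 0.098741, "n": 2}   # k3
- {source: C8b, target: C8b, sign: 1, k: 0.035827, j: 0.09, "n": 2}   # k4
- {source: RIP1, target: C8b, sign: 1, k: 0.3, j: 0.841967, "n": 2}   # k5
- {source: RIP3, target: C8b, sign: -1, k: 3.59312, j: 22.9783, "n": 2}   # k6
- {source: RIP1, target: RIP3, sign: 1, k: 2.73977, j: 0.0730084, "n": 2}   # k7
- {source: RIP3, target: RIP3, sign: 1, k: 0.180418, j: 0.354992, "n": 3}   # k8
- {source: C8b, target: RIP3, sign: -1, k: 40.2928, j: 1.11233, "n": 2}   # k9
input: RIP1
output: RIP3
s: 1.0
denominator: j
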