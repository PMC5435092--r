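# Case definitions: ICPC-1 episode codes and ATC prescription prefixes.
# Prescriptions match by prefix (any R03xxx matches R03).
eczema:
  icpc: S87
  atc: [D07]
asthma:
  icpc: R96
  atc: [R03]
rhinitis:
  icpc: R97
  atc: [R01AC, R01AD, R06]
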