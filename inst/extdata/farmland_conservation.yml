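# Farmland conservation: urban growth slowed to the urban-population growth
# rate, farmland protected (non-decreasing, fed by consolidation of
# abandoned rural settlement, which declines).
name: farmland_conservation
rates:
  urban: 1.45
  rural_residential: -1.0
  farmland: 0.07
targets: {}
forbidden:
  - [water, urban]
protected:
  - farmland
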