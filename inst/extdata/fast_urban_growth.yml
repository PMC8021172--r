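# Fast urban growth: urban land keeps expanding at its observed rate during
# the rapid-urbanisation decade; the other built environment classes also
# grow, absorbing farmland and ecological land.
name: fast_urban_growth
rates:
  urban: 5.68
  rural_residential: 0.5
  industrial_traffic: 1.0
targets: {}
forbidden: []
protected: []
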