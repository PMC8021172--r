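# Ecological conservation: urban land no longer grows, rural settlement and
# industrial/traffic land shrink, woodland/grassland/water are protected and
# absorb the released area.
name: ecological_conservation
rates:
  urban: 0.0
  rural_residential: -1.1
  industrial_traffic: -1.5
targets: {}
forbidden:
  - [woodland, urban]
  - [water, urban]
protected:
  - woodland
  - grassland
  - water
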