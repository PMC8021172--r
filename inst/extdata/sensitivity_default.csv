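landuse,habitat,farmland,urban,rural_residential,industrial_traffic
farmland,0.3,0,0.6,0.4,0.5
woodland,1,0.7,0.9,0.8,0.9
grassland,0.6,0.4,0.5,0.4,0.5
water,0.8,0.7,0.9,0.8,0.9
urban,0,0,0,0,0
rural_residential,0,0,0,0,0
industrial_traffic,0,0,0,0,0
barren,0.2,0.2,0.5,0.4,0.3
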