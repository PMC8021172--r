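threat,max_dist_km,weight,decay
farmland,6,0.6,exponential
urban,10,0.9,exponential
rural_residential,8,0.7,exponential
industrial_traffic,12,1,linear
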