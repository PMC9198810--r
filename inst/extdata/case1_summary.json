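{"compartment":["S","E","W","I","R"],"peak":[120,37.5999495040318,18.4297525543363,19.0244517492594,184.09068387555],"peak_time":[0,1,1.5,1.5,500],"outbreak_peak":[120,37.5999495040318,18.4297525543363,19.0244517492594,184.09068387555],"outbreak_peak_time":[0,1,1.5,1.5,500],"time_below_threshold":[1.29401159511862,0,6.94922036752768,7.39905452603103,0],"terminal":[3.40885638518255,0.000139351256780065,9.51726515749399e-05,0.00012006355332493,184.09068387555]}
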