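{"compartment":["S","E","W","I","R"],"peak":[120,59.0028923564017,15.2045579218266,29.4929001335045,164.170333584591],"peak_time":[0,1,1.5,1.5,377.5],"outbreak_peak":[2.77529810505451,59.0028923564017,15.2045579218266,29.4929001335045,164.170333584591],"outbreak_peak_time":[12,1,1.5,1.5,377.5],"time_below_threshold":[1.35332668217027,0,null,null,0],"terminal":[2.77300000000001,7.27298787242169,2.45156894576011,6.1897769126993,164.170333584591]}
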