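{"compartment":["S","E","W","I","R"],"peak":[120,61.7883487372715,15,30.9802548013784,184.08100793618],"peak_time":[0,1,0,1.5,400],"outbreak_peak":[2.53937455801793,61.7883487372715,12.2111194795511,30.9802548013784,184.08100793618],"outbreak_peak_time":[12.5,1,1,1.5,400],"time_below_threshold":[220.481590438049,223.731246057769,223.999428462378,224.844101385852,null],"terminal":[3.39894544180695,0.00602367016179998,0.00412179712215636,0.00519924844994823,184.08100793618]}
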