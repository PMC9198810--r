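{"compartment":["S","E","W","I","R"],"peak":[120,51.6101260699208,23.4957054657282,25.6166848473031,184.081052397901],"peak_time":[0,1,1.5,1.5,400],"outbreak_peak":[3.4849810482135,51.6101260699208,23.4957054657282,25.6166848473031,184.081052397901],"outbreak_peak_time":[10.5,1,1.5,1.5,400],"time_below_threshold":[null,223.438632179617,223.902692705073,224.486819586474,null],"terminal":[3.39898921354294,0.00599770203298308,0.00410399351498144,0.00517679330613656,184.081052397901]}
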