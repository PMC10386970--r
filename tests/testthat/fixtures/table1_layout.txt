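Measure                PS                   NS                  
----------------------------------------------------------------
Climbing rate (uV/s)     -17.52 +/- 0.77      -16.52 +/- 0.76   
Peak latency (ms)        687.43 +/- 18.65     774.05 +/- 21.96  
Peak amplitude (uV)      -10.86 +/- 0.21      -11.34 +/- 0.26   
Mean amplitude (uV)       -4.42 +/- 0.12       -4.79 +/- 0.23   
PSE (ms)                 817.61 +/- 34.41     919.55 +/- 36.84  
JND (ms)                  99.35 +/- 4.51       69.24 +/- 19.62  
n participants         6                    6                   
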