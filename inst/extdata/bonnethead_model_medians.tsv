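model	description	median_AIC
sc2ns	No split, two epochs	1948.72
sc1ns	No split, one epoch	1950.75
sc3ns	No split, three epochs	1952.63
s2msm	One split, one epoch with symmetric migration	1968.08
sc2el	One split, two epochs with asymmetric migration	1998.72
s2m	One split, one epoch with asymmetric migration	2022.84
sc2elsm	One split, two epochs with symmetric migration	2261.93
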