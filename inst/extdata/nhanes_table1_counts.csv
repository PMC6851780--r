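maneuver,n_performed,n_accepted,n_excluded
1,6845,NA,NA
2,7169,NA,NA
3,7198,2163,5035
4,5035,1848,3187
5,3187,1136,2051
6,2051,687,1164
7,1364,394,970
8,970,968,2
9,2,NA,NA
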