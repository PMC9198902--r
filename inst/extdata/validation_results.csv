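subject,method,phase,accuracyPct,itrBpm
S1,ALPHA,validation,75.83,88.72
S2,ALPHA,validation,93.33,126.15
S3,ALPHA,validation,98.33,139.67
S4,ALPHA,validation,96.67,134.90
S5,ALPHA,validation,98.75,141.04
S6,ALPHA,validation,90.00,118.55
S7,ALPHA,validation,87.08,111.91
S8,ALPHA,validation,88.33,114.48
S9,ALPHA,validation,45.42,40.10
S1,TRCA,validation,55.83,55.00
S2,TRCA,validation,80.00,97.29
S3,TRCA,validation,99.17,142.41
S4,TRCA,validation,90.42,119.27
S5,TRCA,validation,97.50,137.40
S6,TRCA,validation,67.08,72.85
S7,TRCA,validation,75.00,87.26
S8,TRCA,validation,90.83,120.30
S9,TRCA,validation,43.33,37.25
S1,ALPHA,offline,86.81,114.42
S2,ALPHA,offline,87.01,112.03
S3,ALPHA,offline,92.71,126.62
S4,ALPHA,offline,88.89,116.64
S5,ALPHA,offline,92.85,125.98
S6,ALPHA,offline,96.94,135.84
S7,ALPHA,offline,77.78,93.46
S8,ALPHA,offline,84.79,107.13
S9,ALPHA,offline,67.22,74.37
S1,TRCA,offline,87.08,112.16
S2,TRCA,offline,85.28,107.96
S3,TRCA,offline,88.47,117.75
S4,TRCA,offline,71.52,84.41
S5,TRCA,offline,97.36,137.40
S6,TRCA,offline,89.86,119.99
S7,TRCA,offline,30.28,21.60
S8,TRCA,offline,74.72,88.03
S9,TRCA,offline,50.00,49.10
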