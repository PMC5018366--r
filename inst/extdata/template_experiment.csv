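# Checkerboard template: first row = doses of drug A (columns), first
# column = doses of drug B (rows), body = response in % of untreated
# control (100 = no effect). The top-left cell may name the drugs as
# "drug A / drug B". Save replicates as <name>_rep1.csv, <name>_rep2.csv, ...
Drug A / Drug B,0,0.0316,0.1,0.316,1,3.16,10,31.6
0,100,96,90,75,52,30,15,8
0.0316,97,93,86,70,48,27,13,7
0.1,92,88,80,64,43,24,11,6
0.316,81,76,68,53,35,19,9,5
1,62,58,51,39,26,14,7,4
3.16,42,39,34,26,17,10,5,3
10,26,24,21,16,11,6,3,2
31.6,16,15,13,10,7,4,2,1
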