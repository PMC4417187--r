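# Reconstructed relative deletion-propensity calibration, lambda-phage style.
# Not measured data: a log-linear curve standing in for deletion frequencies
# between engineered direct repeats in bacteriophage lambda DNA. Replace with
# measured frequencies via mutagenicity_model(path = ...).
# log2_slope: 1.0
# log2_at_min: 0.0
length	weight
10	1
11	2
12	4
13	8
14	16
15	32
16	64
17	128
18	256
19	512
20	1024
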