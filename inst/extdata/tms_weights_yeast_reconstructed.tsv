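# Reconstructed relative deletion-propensity calibration, yeast-mtDNA style.
# Not measured data: a shallower log-linear curve standing in for repeat
# length vs deletion frequency in yeast mitochondrial DNA. Replace with
# measured frequencies via mutagenicity_model(path = ...).
# log2_slope: 0.68
# log2_at_min: 0.0
length	weight
10	1
11	1.602
12	2.566
13	4.111
14	6.587
15	10.556
16	16.91
17	27.1
18	43.41
19	69.55
20	111.43
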