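chr1	50	120	peakA
chr2	0	30	peakB
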