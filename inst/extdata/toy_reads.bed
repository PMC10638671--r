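chr1	10	60
chr1	100	150
chr1	200	250
chr2	5	55
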