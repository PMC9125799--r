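Virus	length	Yeast	Yeastpos	Yeastneg
SbOMV1 RNA1	2392	132,412	13,262	119,150
SbOMV1 RNA2	1726	164,614	14,410	150,204
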