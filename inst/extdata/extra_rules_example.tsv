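gene	variant	pos	allele
CSN1S1	C	87157262	G
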