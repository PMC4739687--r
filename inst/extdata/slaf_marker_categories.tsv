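category	n
SNP	4326
EPSNP	99
INDEL	55
no_polymorphism	39538
unknown	888
repeat	1181
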