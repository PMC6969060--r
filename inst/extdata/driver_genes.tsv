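#gene
APC
TP53
KRAS
NRAS
PIK3CA
BRAF
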