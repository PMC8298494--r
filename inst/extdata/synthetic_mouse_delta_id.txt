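# synthetic mouse delta-cell ID gene list (9 genes)
Sst
Hhex
SynD001
SynD002
SynD003
SynD004
SynD005
SynD006
SynD007
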