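name	consensus
CArG	CCW{6}GG
PBE-box	CACATG
G-box	CACGTG
E-box	CANNTG
ACE-motif	ACGTG
CA-hybrid	GACGTA
CG-hybrid	GACGTG
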