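protein	site	sequon
E-cadherin	N558	NSTY
E-cadherin	N570	NGSP
E-cadherin	N622	NTSP
E-cadherin	N637	NWTI
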