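protein	site	sequon
EGFR	N56	NNCE
EGFR	N73	NYDL
EGFR	N128	NKTG
EGFR	N175	NMSM
EGFR	N196	NGSC
EGFR	N352	NATN
EGFR	N361	NCTS
EGFR	N413	NRTD
EGFR	N444	NITS
EGFR	N528	NVSR
EGFR	N568	NITC
EGFR	N603	NNTL
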