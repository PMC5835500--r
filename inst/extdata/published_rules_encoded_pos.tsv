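pattern	consequent	confidence_pct	thresholds
<A,-5><O,1><L,2>	N+	100	5
<A,-2><O,1><L,2>	N+	100	5
<N,-4><O,1><L,2>	N+	100	5
<O,1><L,2><N,3>	N+	100	5
<O,1><L,2><N,5>	N+	100	5
<P,-9><O,1><L,2>	N+	100	5
<P,-3><O,1><L,2>	N+	100	5
<O,1><L,2><P,9>	N+	100	5
<O,1><L,2><P,10>	N+	100	5
<A,-5><L,2>	N+	100	10
<A,-2><L,2>	N+	77.25	10
<A,-1><L,2>	N+	100	10
<L,2><A,3>	N+	74.88	10
<L,2><A,10>	N+	77.31	10
<N,-4><L,2>	N+	100	10
<L,2><N,3>	N+	100	10
<L,2><N,5>	N+	100	10
<P,-9><L,2>	N+	100	10
<P,-3><L,2>	N+	100	10
<L,2><P,9>	N+	100	10
<L,2><P,10>	N+	100	10
<O,1><L,2>	N+	100	15,20,25,30,35,40
<L,2>	N+	76.12	45,50,55,60,65,70,75,80,85,90,95
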