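pattern	consequent	confidence_pct	thresholds
<L,-5><T,2>	N+	100	5
<T,2><L,3>	N+	100	5
<V,1><T,2>	N+	100	5
<T,2><V,3>	N+	100	5
<L,-5>	N+	100	10
<L,3>	N+	100	10
<S,2>	N+	100	10,15,20,25,30,35,40
<T,2>	N+	85.87	10,15,20,25,30,35,40,45,50,55
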