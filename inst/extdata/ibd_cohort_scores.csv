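patient_id,disease,therapy,phase,activity_score,rhi
1,UC,naive,t0,8,17
1,UC,naive,t1,4,8
1,UC,naive,t2,4,8
2,UC,naive,t0,8,12
2,UC,naive,t1,2,6
2,UC,naive,t2,2,6
3,CD,naive,t0,6,6
3,CD,naive,t1,6,6
3,CD,naive,t2,4,6
4,UC,anti-TNF,t0,6,14
4,UC,anti-TNF,t1,3,1
4,UC,anti-TNF,t2,4,1
5,CD,naive,t0,7,12
5,CD,naive,t1,5,1
5,CD,naive,t2,1,1
6,CD,anti-TNF,t0,5,6
6,CD,anti-TNF,t1,4,6
6,CD,anti-TNF,t2,3,6
7,UC,anti-TNF,t0,11,23
7,UC,anti-TNF,t1,1,6
7,UC,anti-TNF,t2,2,6
8,CD,naive,t0,10,17
8,CD,naive,t1,1,6
8,CD,naive,t2,0,7
9,UC,anti-TNF,t0,9,23
9,UC,anti-TNF,t1,3,11
9,UC,anti-TNF,t2,2,6
10,UC,naive,t0,7,23
10,UC,naive,t1,3,16
10,UC,naive,t2,2,9
11,UC,anti-TNF,t0,6,19
11,UC,anti-TNF,t1,6,6
11,UC,anti-TNF,t2,4,6
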