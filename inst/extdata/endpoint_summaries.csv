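endpoint,unit,statistic,t0,t1,t2,control
teer,Ohm.cm2,mean,12.27,18.12,18.36,21.15
teer,Ohm.cm2,median,12.80,16.80,18.30,18.50
teer,Ohm.cm2,std,3.15,7.23,4.86,9.14
teer,Ohm.cm2,minimum,7.50,10.00,13.25,10.00
teer,Ohm.cm2,maximum,17.40,34.50,28.00,39.32
pm,1e-6.cm2.per.s,mean,0.883,0.814,0.735,0.686
pm,1e-6.cm2.per.s,median,1.030,0.974,0.605,0.528
pm,1e-6.cm2.per.s,std,0.451,0.446,0.552,0.365
pm,1e-6.cm2.per.s,minimum,0.080,0.054,0.032,0.249
pm,1e-6.cm2.per.s,maximum,1.510,1.450,1.760,1.270
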