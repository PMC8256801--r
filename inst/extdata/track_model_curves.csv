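energy_keV,ev_per_event,cluster_sigma_nm,cluster_spacing_nm
1,17.8571,1.68657424788123,7.086
2,18.747,1.70652270327345,12.173
5,20.069,1.09167661104154,25.086
10,21.1999,1.26648034764153,46.087
20,22.4659,1.01776231466171,80.235
50,24.3914,1.17054911454737,182.025
100,26.0824,1.06201553500339,316.534
200,28.0254,1.17388249714632,500.454
500,31.0867,1.14767293196303,740.16
1000,33.8868,1.22284663716433,891.758
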