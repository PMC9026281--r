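patient_id,diagnosis,mean,median,sd,skewness,kurtosis
01,Relapsed myeloma,-63.9,-72.0,47.8,1.2,4.6
02,Relapsed myeloma,-59.2,-64.0,45.4,1.6,26.8
03,Relapsed myeloma,-63.6,-77.0,100.0,13.9,315.2
04,New myeloma,-39.1,-35.0,47.5,1.1,17.8
05,Relapsed myeloma,-54.3,-58.0,45.3,0.5,0.3
06,Relapsed myeloma,-47.4,-50.0,54.6,0.6,1.4
07,New myeloma,-82.5,-91.0,49.4,1.0,3.4
08,Relapsed myeloma,-53.9,-55.0,46.6,1.1,7.7
09,Relapsed myeloma,-53.3,-55.0,36.4,0.9,8.4
10,Relapsed myeloma,-64.6,-69.0,45.4,1.3,5.3
11,New myeloma,-26.1,-28.0,96.7,7.0,87.2
12,Relapsed myeloma,-25.5,-25.0,71.2,2.7,25.1
13,MGUS - light chain,-58.1,-79.0,108.8,5.0,31.1
14,Relapsed myeloma,-41.9,-46.0,80.7,7.6,96.2
15,MGUS - IgA,-72.2,-79.0,51.8,1.6,10.6
16,New myeloma,-62.3,-83.0,143.3,9.3,121.6
17,Relapsed myeloma,-75.8,-83.0,58.0,2.8,26.4
18,MGUS - IgG kappa,-79.7,-82.0,44.4,0.2,0.4
19,Relapsed myeloma,-59.9,-63.0,49.4,3.5,69.2
20,New myeloma,-66.3,-84.0,81.3,9.8,224.4
21,New myeloma,-77.5,-83.0,49.2,2.4,28.2
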