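set,method,variant,systems,models,positives,positive_pct,negatives,ps_mean,ps_sd
bound,ProPOSE,docking,231,22515,868,3.9,21647,3.8,3.5
bound,ZDOCK,docking,231,23056,629,2.7,22427,2.7,5.5
bound,PIPER,docking,231,23100,2266,9.8,20834,9.8,20.0
bound,ClusPro,docking,231,7712,168,2.2,7544,0.7,1.0
unbound,ProPOSE,docking,25,2500,30,1.2,2470,1.2,1.8
unbound,ZDOCK,docking,25,2500,62,2.5,2438,2.5,3.8
unbound,PIPER,docking,25,2440,179,7.3,2261,7.2,15.9
unbound,ClusPro,docking,25,806,20,2.5,786,0.8,1.5
bound,ProPOSE,af2,231,22515,974,4.3,21541,4.2,4.3
bound,ZDOCK,af2,231,23056,740,3.2,22316,3.2,5.9
bound,PIPER,af2,231,23100,2996,13.0,20104,13.0,21.9
bound,ClusPro,af2,231,7712,264,3.4,7448,1.1,1.1
unbound,ProPOSE,af2,25,2500,34,1.4,2466,1.4,2.2
unbound,ZDOCK,af2,25,2500,63,2.5,2437,2.5,3.9
unbound,PIPER,af2,25,2440,236,9.7,2204,9.4,17.0
unbound,ClusPro,af2,25,806,29,3.6,777,1.2,1.6
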