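set,scenario,dose,p_dlt,is_mtd,target
binary-0.2,1,1,0.2,1,0.2
binary-0.2,1,2,0.25,0,0.2
binary-0.2,1,3,0.35,0,0.2
binary-0.2,1,4,0.45,0,0.2
binary-0.2,1,5,0.5,0,0.2
binary-0.2,2,1,0.2,1,0.2
binary-0.2,2,2,0.3,0,0.2
binary-0.2,2,3,0.4,0,0.2
binary-0.2,2,4,0.5,0,0.2
binary-0.2,2,5,0.6,0,0.2
binary-0.2,3,1,0.15,0,0.2
binary-0.2,3,2,0.2,1,0.2
binary-0.2,3,3,0.25,0,0.2
binary-0.2,3,4,0.35,0,0.2
binary-0.2,3,5,0.45,0,0.2
binary-0.2,4,1,0.15,0,0.2
binary-0.2,4,2,0.2,1,0.2
binary-0.2,4,3,0.3,0,0.2
binary-0.2,4,4,0.45,0,0.2
binary-0.2,4,5,0.55,0,0.2
binary-0.2,5,1,0.1,0,0.2
binary-0.2,5,2,0.2,1,0.2
binary-0.2,5,3,0.25,0,0.2
binary-0.2,5,4,0.35,0,0.2
binary-0.2,5,5,0.45,0,0.2
binary-0.2,6,1,0.1,0,0.2
binary-0.2,6,2,0.2,1,0.2
binary-0.2,6,3,0.3,0,0.2
binary-0.2,6,4,0.4,0,0.2
binary-0.2,6,5,0.55,0,0.2
binary-0.2,7,1,0.08,0,0.2
binary-0.2,7,2,0.15,0,0.2
binary-0.2,7,3,0.2,1,0.2
binary-0.2,7,4,0.25,0,0.2
binary-0.2,7,5,0.35,0,0.2
binary-0.2,8,1,0.08,0,0.2
binary-0.2,8,2,0.15,0,0.2
binary-0.2,8,3,0.2,1,0.2
binary-0.2,8,4,0.3,0,0.2
binary-0.2,8,5,0.45,0,0.2
binary-0.2,9,1,0.05,0,0.2
binary-0.2,9,2,0.1,0,0.2
binary-0.2,9,3,0.2,1,0.2
binary-0.2,9,4,0.25,0,0.2
binary-0.2,9,5,0.35,0,0.2
binary-0.2,10,1,0.05,0,0.2
binary-0.2,10,2,0.1,0,0.2
binary-0.2,10,3,0.2,1,0.2
binary-0.2,10,4,0.3,0,0.2
binary-0.2,10,5,0.45,0,0.2
binary-0.2,11,1,0.05,0,0.2
binary-0.2,11,2,0.1,0,0.2
binary-0.2,11,3,0.15,0,0.2
binary-0.2,11,4,0.2,1,0.2
binary-0.2,11,5,0.25,0,0.2
binary-0.2,12,1,0.05,0,0.2
binary-0.2,12,2,0.1,0,0.2
binary-0.2,12,3,0.15,0,0.2
binary-0.2,12,4,0.2,1,0.2
binary-0.2,12,5,0.3,0,0.2
binary-0.2,13,1,0.02,0,0.2
binary-0.2,13,2,0.06,0,0.2
binary-0.2,13,3,0.1,0,0.2
binary-0.2,13,4,0.2,1,0.2
binary-0.2,13,5,0.25,0,0.2
binary-0.2,14,1,0.02,0,0.2
binary-0.2,14,2,0.06,0,0.2
binary-0.2,14,3,0.1,0,0.2
binary-0.2,14,4,0.2,1,0.2
binary-0.2,14,5,0.3,0,0.2
binary-0.2,15,1,0.02,0,0.2
binary-0.2,15,2,0.05,0,0.2
binary-0.2,15,3,0.07,0,0.2
binary-0.2,15,4,0.1,0,0.2
binary-0.2,15,5,0.2,1,0.2
binary-0.2,16,1,0.01,0,0.2
binary-0.2,16,2,0.06,0,0.2
binary-0.2,16,3,0.1,0,0.2
binary-0.2,16,4,0.15,0,0.2
binary-0.2,16,5,0.2,1,0.2
binary-0.3,1,1,0.3,1,0.3
binary-0.3,1,2,0.4,0,0.3
binary-0.3,1,3,0.5,0,0.3
binary-0.3,1,4,0.6,0,0.3
binary-0.3,1,5,0.7,0,0.3
binary-0.3,2,1,0.3,1,0.3
binary-0.3,2,2,0.45,0,0.3
binary-0.3,2,3,0.6,0,0.3
binary-0.3,2,4,0.7,0,0.3
binary-0.3,2,5,0.8,0,0.3
binary-0.3,3,1,0.2,0,0.3
binary-0.3,3,2,0.3,1,0.3
binary-0.3,3,3,0.4,0,0.3
binary-0.3,3,4,0.5,0,0.3
binary-0.3,3,5,0.6,0,0.3
binary-0.3,4,1,0.2,0,0.3
binary-0.3,4,2,0.3,1,0.3
binary-0.3,4,3,0.45,0,0.3
binary-0.3,4,4,0.6,0,0.3
binary-0.3,4,5,0.7,0,0.3
binary-0.3,5,1,0.15,0,0.3
binary-0.3,5,2,0.3,1,0.3
binary-0.3,5,3,0.4,0,0.3
binary-0.3,5,4,0.5,0,0.3
binary-0.3,5,5,0.6,0,0.3
binary-0.3,6,1,0.15,0,0.3
binary-0.3,6,2,0.3,1,0.3
binary-0.3,6,3,0.45,0,0.3
binary-0.3,6,4,0.6,0,0.3
binary-0.3,6,5,0.7,0,0.3
binary-0.3,7,1,0.12,0,0.3
binary-0.3,7,2,0.2,0,0.3
binary-0.3,7,3,0.3,1,0.3
binary-0.3,7,4,0.4,0,0.3
binary-0.3,7,5,0.5,0,0.3
binary-0.3,8,1,0.12,0,0.3
binary-0.3,8,2,0.2,0,0.3
binary-0.3,8,3,0.3,1,0.3
binary-0.3,8,4,0.45,0,0.3
binary-0.3,8,5,0.6,0,0.3
binary-0.3,9,1,0.05,0,0.3
binary-0.3,9,2,0.15,0,0.3
binary-0.3,9,3,0.3,1,0.3
binary-0.3,9,4,0.4,0,0.3
binary-0.3,9,5,0.5,0,0.3
binary-0.3,10,1,0.05,0,0.3
binary-0.3,10,2,0.15,0,0.3
binary-0.3,10,3,0.3,1,0.3
binary-0.3,10,4,0.45,0,0.3
binary-0.3,10,5,0.6,0,0.3
binary-0.3,11,1,0.05,0,0.3
binary-0.3,11,2,0.12,0,0.3
binary-0.3,11,3,0.2,0,0.3
binary-0.3,11,4,0.3,1,0.3
binary-0.3,11,5,0.4,0,0.3
binary-0.3,12,1,0.05,0,0.3
binary-0.3,12,2,0.12,0,0.3
binary-0.3,12,3,0.2,0,0.3
binary-0.3,12,4,0.3,1,0.3
binary-0.3,12,5,0.45,0,0.3
binary-0.3,13,1,0.02,0,0.3
binary-0.3,13,2,0.08,0,0.3
binary-0.3,13,3,0.15,0,0.3
binary-0.3,13,4,0.3,1,0.3
binary-0.3,13,5,0.4,0,0.3
binary-0.3,14,1,0.02,0,0.3
binary-0.3,14,2,0.08,0,0.3
binary-0.3,14,3,0.15,0,0.3
binary-0.3,14,4,0.3,1,0.3
binary-0.3,14,5,0.45,0,0.3
binary-0.3,15,1,0.02,0,0.3
binary-0.3,15,2,0.1,0,0.3
binary-0.3,15,3,0.15,0,0.3
binary-0.3,15,4,0.2,0,0.3
binary-0.3,15,5,0.3,1,0.3
binary-0.3,16,1,0.01,0,0.3
binary-0.3,16,2,0.04,0,0.3
binary-0.3,16,3,0.08,0,0.3
binary-0.3,16,4,0.15,0,0.3
binary-0.3,16,5,0.3,1,0.3
binary-samplesize,1,1,0.01,0,0.2
binary-samplesize,1,2,0.1,0,0.2
binary-samplesize,1,3,0.2,1,0.2
binary-samplesize,1,4,0.3,0,0.2
binary-samplesize,1,5,0.35,0,0.2
binary-samplesize,2,1,0.01,0,0.2
binary-samplesize,2,2,0.18,0,0.2
binary-samplesize,2,3,0.2,1,0.2
binary-samplesize,2,4,0.3,0,0.2
binary-samplesize,2,5,0.35,0,0.2
binary-samplesize,3,1,0.01,0,0.3
binary-samplesize,3,2,0.2,0,0.3
binary-samplesize,3,3,0.3,1,0.3
binary-samplesize,3,4,0.4,0,0.3
binary-samplesize,3,5,0.5,0,0.3
binary-samplesize,4,1,0.01,0,0.3
binary-samplesize,4,2,0.25,0,0.3
binary-samplesize,4,3,0.3,1,0.3
binary-samplesize,4,4,0.4,0,0.3
binary-samplesize,4,5,0.5,0,0.3
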