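t1_category,normal,mild,moderate,moderately_severe
normal,143,14,0,0
mild,32,40,5,0
moderate,3,20,5,1
moderately_severe,1,1,2,0
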