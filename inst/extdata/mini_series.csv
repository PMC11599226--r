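time,value,label
0,-0.75,0
0.0078125,-0.6,0
0.015625,0.5,1
0.0234375,-0.8,0
0.03125,-0.75,0
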