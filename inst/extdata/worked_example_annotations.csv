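time_s,code
793.6,vf
805.2,c1
887.2,c2
903.3,d1
908.3,d2
908.3,pe
938.8,c1
944.0,vf
1062.0,c2
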