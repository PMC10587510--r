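sample_id,tobacco_type,label
apple,maassel,Apple
blueberry,maassel,Blueberry
orange,maassel,Orange
khansar,traditional,Khansar
borazjan,traditional,Borazjan
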