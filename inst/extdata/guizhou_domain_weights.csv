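class_code,class_name,weight
1,farmland,0.1470
2,forest,0.1841
3,grassland,0.0774
4,aquatic,0.0055
5,settlement,0.0117
6,other,0.0001
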