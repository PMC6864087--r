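# Vendor-computed descriptor values printed in the source tables/text, kept
# as reference inputs (the open contribution schemes in this package are not
# expected to reproduce vendor ClogP/LogS/pKa bit-for-bit; TPSA is).
id,property,value
PP1,psa,66.84
HR1,psa,49.77
HR36,clogp,-0.31
HR36,logs,0.88
HR36,logbb,-0.6
HR36,mpo,4.0
HR32,mpo,2.97
HR35,mpo,4.41
PP1,mp,39.25
HR9,mp,37.05
HR11,mp,39.36
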