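domain	lnL_M8a	lnL_M8
zp1_n1	-10234.512	-10226.881
zp2_n1	-15480.220	-15462.304
zp2_n2	-14321.907	-14317.112
zp2_n3	-13912.441	-13911.936
zp3_n	-9875.330	-9875.330
zp4_n1	-11230.774	-11230.912
umod_n	-12789.655	-12786.410
tecta_n	-16544.209	-16543.870
cuzd1_n1	-8321.450	-8319.990
cuzd1_n2	-7990.118	-7989.873
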