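sample	mapped_reads	total_reads	raw_bases	clean_bases
Y11	52786428	54468694	6867532750	6808586750
GH998	54162109	55403332	6992487000	6925416500
L_pool	161503688	165856646	18695867000	18536966000
H_pool	144233962	148295728	21128305000	20732080750
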