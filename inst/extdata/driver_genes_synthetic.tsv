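gene	role	chrom	start	end	hotspots	reg_start	reg_end
CTNNB1	oncogene	chr3	41000000	41050000	41010101,41010120	NA	NA
MYCN	oncogene	chr2	16000000	16010000	16005001	NA	NA
FOXR2	oncogene	chr5	55000000	55005000	NA	54990000	55000000
TERT	oncogene	chr5	1250000	1300000	1295113,1295135	NA	NA
WT1	recessive	chr11	32400000	32460000	NA	NA	NA
REST	recessive	chr4	57770000	57800000	NA	NA	NA
TP53	recessive	chr17	7570000	7590000	NA	NA	NA
AMER1	recessive	chr21	10000000	10020000	NA	NA	NA
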