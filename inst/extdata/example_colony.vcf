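##fileformat=VCFv4.2
##source=digenicmap
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
1	1000000	1:1e+06	A	G	.	PASS	.	GT	1/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1	1/1	0/0
1	1050000	1:1050000	A	G	.	PASS	.	GT	1/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1	./.	0/0
1	1100000	1:1100000	A	G	.	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/1	0/0
1	1150000	1:1150000	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	1/1	1/1	0/1	0/1	0/1	1/1
1	1200000	1:1200000	A	G	.	PASS	.	GT	0/1	1/1	1/1	0/1	1/1	0/1	0/1	0/1	0/1	1/1
1	1250000	1:1250000	A	G	.	PASS	.	GT	1/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1	1/1	0/0
1	1750000	1:1750000	A	G	.	PASS	.	GT	1/1	1/1	0/1	./.	1/1	0/1	0/1	1/1	1/1	1/1
1	1800000	1:1800000	A	G	.	PASS	.	GT	0/1	1/1	1/1	1/1	0/0	0/1	1/1	0/1	0/1	0/1
1	1850000	1:1850000	A	G	.	PASS	.	GT	0/0	./.	0/1	1/1	0/0	0/1	0/1	0/0	0/0	0/0
1	1900000	1:1900000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	1950000	1:1950000	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
1	2000000	1:2e+06	A	G	.	PASS	.	GT	0/1	0/0	0/0	0/0	1/1	0/1	0/0	0/1	0/1	0/1
2	1000000	2:1e+06	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/1	0/1	1/1	1/1	0/1	0/1
2	1050000	2:1050000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/1	0/1	1/1	1/1	0/1	0/1
2	1100000	2:1100000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/1	0/1	1/1	1/1	0/1	0/1
2	1150000	2:1150000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
2	1200000	2:1200000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	./.	0/1	1/1	1/1	0/1	0/1
2	1250000	2:1250000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/1	0/1	1/1	1/1	0/1	0/1
2	1750000	2:1750000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
2	1800000	2:1800000	A	G	.	PASS	.	GT	0/1	0/1	1/1	1/1	1/1	0/1	0/1	0/0	0/1	0/1
2	1850000	2:1850000	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	1/1	0/0	0/0	0/0	0/1	0/0
2	1900000	2:1900000	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
2	1950000	2:1950000	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/1	0/1	1/1	0/1	0/1
2	2000000	2:2e+06	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
3	1000000	3:1e+06	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0
3	1050000	3:1050000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	0/1	0/1	0/1	0/1	0/1	0/1
3	1100000	3:1100000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0
3	1150000	3:1150000	A	G	.	PASS	.	GT	0/0	1/1	1/1	0/0	1/1	0/1	0/1	0/1	0/1	0/1
3	1200000	3:1200000	A	G	.	PASS	.	GT	1/1	0/0	0/0	1/1	0/1	0/1	0/1	0/1	0/1	0/1
3	1250000	3:1250000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
3	1750000	3:1750000	A	G	.	PASS	.	GT	./.	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/1
3	1800000	3:1800000	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
3	1850000	3:1850000	A	G	.	PASS	.	GT	0/1	1/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1
3	1900000	3:1900000	A	G	.	PASS	.	GT	0/0	0/0	1/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0
3	1950000	3:1950000	A	G	.	PASS	.	GT	1/1	1/1	0/0	0/1	0/1	0/1	0/1	1/1	1/1	1/1
3	2000000	3:2e+06	A	G	.	PASS	.	GT	0/1	0/0	1/1	0/1	1/1	1/1	0/1	0/1	0/1	0/1
4	1000000	4:1e+06	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
4	1050000	4:1050000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/1
4	1100000	4:1100000	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/0	0/1	1/1	0/1	1/1	0/0
4	1150000	4:1150000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/1	./.	0/1	0/0	0/1
4	1200000	4:1200000	A	G	.	PASS	.	GT	0/1	./.	0/1	0/1	0/0	0/1	1/1	0/1	1/1	0/0
4	1250000	4:1250000	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/0	0/1	1/1	0/1	1/1	0/0
4	1750000	4:1750000	A	G	.	PASS	.	GT	1/1	./.	1/1	1/1	0/1	1/1	1/1	1/1	0/1	0/1
4	1800000	4:1800000	A	G	.	PASS	.	GT	1/1	0/1	1/1	1/1	0/1	1/1	1/1	1/1	0/1	0/1
4	1850000	4:1850000	A	G	.	PASS	.	GT	1/1	0/1	1/1	./.	0/1	1/1	1/1	1/1	0/1	0/1
4	1900000	4:1900000	A	G	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/1
4	1950000	4:1950000	A	G	.	PASS	.	GT	0/1	0/1	0/1	1/1	1/1	0/1	0/1	0/1	0/1	0/1
4	2000000	4:2e+06	A	G	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/1
5	1000000	5:1e+06	A	G	.	PASS	.	GT	0/1	0/1	1/1	1/1	1/1	1/1	1/1	0/1	0/1	1/1
5	1050000	5:1050000	A	G	.	PASS	.	GT	0/1	0/1	0/1	1/1	1/1	0/1	0/1	0/0	0/0	1/1
5	1100000	5:1100000	A	G	.	PASS	.	GT	0/1	0/1	./.	1/1	1/1	0/1	0/1	0/0	0/0	1/1
5	1150000	5:1150000	A	G	.	PASS	.	GT	0/1	0/1	0/1	1/1	1/1	0/1	0/1	0/0	0/0	1/1
5	1200000	5:1200000	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	./.	0/0
5	1250000	5:1250000	A	G	.	PASS	.	GT	0/1	0/1	0/1	1/1	1/1	0/1	0/1	0/0	0/0	1/1
5	1750000	5:1750000	A	G	.	PASS	.	GT	1/1	1/1	0/1	0/1	0/1	1/1	1/1	1/1	1/1	1/1
5	1800000	5:1800000	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
5	1850000	5:1850000	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0
5	1900000	5:1900000	A	G	.	PASS	.	GT	0/1	1/1	1/1	1/1	1/1	0/0	0/1	0/1	0/1	0/1
5	1950000	5:1950000	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	1/1	0/1	0/1	0/1	0/1
5	2000000	5:2e+06	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	./.	0/0	0/0	0/0	0/0
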