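element	mass	abundance
H	1.00782503207	0.999885
H	2.0141017778	0.000115
C	12.0	0.9893
C	13.0033548378	0.0107
N	14.0030740048	0.99636
N	15.0001088982	0.00364
O	15.99491461956	0.99757
O	16.99913170	0.00038
O	17.9991610	0.00205
P	30.97376163	1.0
S	31.97207100	0.9499
S	32.97145876	0.0075
S	33.96786690	0.0425
S	35.96708076	0.0001
F	18.99840322	1.0
Na	22.9897692809	1.0
Mg	23.9850417	0.7899
Mg	24.98583692	0.1000
Mg	25.982592929	0.1101
Si	27.9769265325	0.92223
Si	28.976494700	0.04685
Si	29.97377017	0.03092
Cl	34.96885268	0.7576
Cl	36.96590259	0.2424
K	38.96370668	0.932581
K	39.96399848	0.000117
K	40.96182576	0.067302
Ca	39.96259098	0.96941
Ca	41.95861801	0.00647
Ca	42.9587666	0.00135
Ca	43.9554818	0.02086
Ca	45.9536926	0.00004
Ca	47.952534	0.00187
Fe	53.9396105	0.05845
Fe	55.9349375	0.91754
Fe	56.9353940	0.02119
Fe	57.9332756	0.00282
Se	73.9224764	0.0089
Se	75.9192136	0.0937
Se	76.9199140	0.0763
Se	77.9173091	0.2377
Se	79.9165213	0.4961
Se	81.9166994	0.0873
Br	78.9183371	0.5069
Br	80.9162906	0.4931
I	126.904473	1.0
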