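snp	pip	in_set
rs0003	0.9990698895	1
rs0004	0.002650153867	0
rs0002	0.002086951329	0
rs0005	0.001973893666	0
rs0007	0.001878141543	0
rs0001	0.001738353773	0
rs0009	0.001703829875	0
rs0010	0.001380940584	0
rs0006	0.001310435613	0
rs0008	0.001231813793	0
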