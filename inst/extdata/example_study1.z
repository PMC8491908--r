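rs0001	2.891376053
rs0002	3.497854506
rs0003	3.888921978
rs0004	4.175631517
rs0005	3.472797141
rs0006	3.049736004
rs0007	2.485855778
rs0008	2.014977463
rs0009	1.415331282
rs0010	1.339780907
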