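rs0001	0
rs0002	0
rs0003	1
rs0004	0
rs0005	0
rs0006	0
rs0007	0
rs0008	0
rs0009	0
rs0010	0
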