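rs0001	1.905102408
rs0002	1.373155396
rs0003	4.228567602
rs0004	1.704816699
rs0005	1.680246835
rs0006	0.2055319289
rs0007	-0.7873501196
rs0008	0.2642234999
rs0009	-0.4220511034
rs0010	-0.2166861082
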