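1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02 3.125000e-02 1.562500e-02 7.812500e-03 3.906250e-03 1.953125e-03
5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02 3.125000e-02 1.562500e-02 7.812500e-03 3.906250e-03
2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02 3.125000e-02 1.562500e-02 7.812500e-03
1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02 3.125000e-02 1.562500e-02
6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02 3.125000e-02
3.125000e-02 6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01 6.250000e-02
1.562500e-02 3.125000e-02 6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01 1.250000e-01
7.812500e-03 1.562500e-02 3.125000e-02 6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01 2.500000e-01
3.906250e-03 7.812500e-03 1.562500e-02 3.125000e-02 6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00 5.000000e-01
1.953125e-03 3.906250e-03 7.812500e-03 1.562500e-02 3.125000e-02 6.250000e-02 1.250000e-01 2.500000e-01 5.000000e-01 1.000000e+00
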