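1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01 5.90490000e-01 5.31441000e-01 4.78296900e-01 4.30467210e-01 3.87420489e-01
9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01 5.90490000e-01 5.31441000e-01 4.78296900e-01 4.30467210e-01
8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01 5.90490000e-01 5.31441000e-01 4.78296900e-01
7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01 5.90490000e-01 5.31441000e-01
6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01 5.90490000e-01
5.90490000e-01 6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01 6.56100000e-01
5.31441000e-01 5.90490000e-01 6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01 7.29000000e-01
4.78296900e-01 5.31441000e-01 5.90490000e-01 6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01 8.10000000e-01
4.30467210e-01 4.78296900e-01 5.31441000e-01 5.90490000e-01 6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00 9.00000000e-01
3.87420489e-01 4.30467210e-01 4.78296900e-01 5.31441000e-01 5.90490000e-01 6.56100000e-01 7.29000000e-01 8.10000000e-01 9.00000000e-01 1.00000000e+00
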