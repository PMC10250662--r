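subject	petco2_normo	petco2_hyper
1	38.0	46.2
2	37.8	44.2
3	42.1	50.5
4	42.6	49.8
5	39.3	47.7
6	33.0	41.6
7	38.7	47.3
8	39.9	47.7
9	38.4	45.5
10	38.2	45.5
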