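# u v w (undirected)
1	2	0.10000000000000001
1	3	0.10000000000000001
2	3	0.10000000000000001
1	4	0.10000000000000001
2	4	0.10000000000000001
3	4	0.10000000000000001
1	5	0.10000000000000001
2	5	0.10000000000000001
3	5	0.10000000000000001
4	5	0.52857142857142858
1	6	0.10000000000000001
2	6	0.10000000000000001
3	6	0.10000000000000001
4	6	0.52857142857142858
5	6	0.52857142857142858
1	7	0.10000000000000001
2	7	0.10000000000000001
3	7	0.10000000000000001
4	7	0.52857142857142858
5	7	0.52857142857142858
6	7	0.52857142857142858
1	8	0.10000000000000001
2	8	0.10000000000000001
3	8	0.10000000000000001
4	8	0.52857142857142858
5	8	0.52857142857142858
6	8	0.52857142857142858
7	8	1.0285714285714285
1	9	0.10000000000000001
2	9	0.10000000000000001
3	9	0.10000000000000001
4	9	0.52857142857142858
5	9	0.52857142857142858
6	9	0.52857142857142858
7	9	1.0285714285714285
8	9	1.0285714285714285
1	10	0.10000000000000001
2	10	0.10000000000000001
3	10	0.10000000000000001
4	10	0.52857142857142858
5	10	0.52857142857142858
6	10	0.52857142857142858
7	10	1.0285714285714285
8	10	1.0285714285714285
9	10	1.0285714285714285
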