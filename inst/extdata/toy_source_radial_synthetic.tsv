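# Synthetic toy radial dose function g(r) for tests (not consensus data)
# columns: r_mm g
1	1.010859
2	1.009646
5	1.006018
10	1.000000
15	0.994018
20	0.988072
30	0.976286
40	0.964640
60	0.941765
80	0.919431
100	0.897628
150	0.845354
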