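# Synthetic toy anisotropy function F(r, theta) for tests (not consensus data)
# grid block: first line theta angles (deg), then rows r_mm F(r,theta...)
theta: 0 15 30 45 60 75 90 105 120 135 150 165 180
5	0.620000	0.748879	0.838253	0.907986	0.958694	0.989606	1.000000	0.989606	0.958694	0.907986	0.838253	0.748879	0.620000
10	0.620000	0.748879	0.838253	0.907986	0.958694	0.989606	1.000000	0.989606	0.958694	0.907986	0.838253	0.748879	0.620000
20	0.620000	0.748879	0.838253	0.907986	0.958694	0.989606	1.000000	0.989606	0.958694	0.907986	0.838253	0.748879	0.620000
50	0.620000	0.748879	0.838253	0.907986	0.958694	0.989606	1.000000	0.989606	0.958694	0.907986	0.838253	0.748879	0.620000
100	0.620000	0.748879	0.838253	0.907986	0.958694	0.989606	1.000000	0.989606	0.958694	0.907986	0.838253	0.748879	0.620000
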