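group	experiment	yield
0 IBS	exp 1	22261320
0 IBS	exp 2	21343080
0 IBS	exp 3	22150200
1 IBS	exp 1	9934316
1 IBS	exp 2	8712575
1 IBS	exp 3	10774206
2 IBS	exp 1	12291694
2 IBS	exp 2	15086179
2 IBS	exp 3	14057537
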