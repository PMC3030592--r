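library	lane	scs_yield	bareback_yield	scs_barcoded	bareback_barcoded
2 IBS	1	12291694	21125492	11647935	19369486
2 IBS	2	15086179	20223717	14410499	19099795
2 IBS	3	15994884	17808757	15490096	17270077
2 IBS	4	14057537	15186074	13834946	14914810
4 IBS	5	18736285	18916427	17840122	18125796
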