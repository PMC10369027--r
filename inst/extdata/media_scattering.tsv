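solution	raw_mean	raw_sd	od595
water	41295	33	NA
PBS	41115	30	0.00
EMM	41652	54	0.00
EMM6S	41362	79	0.00
YE4S	41457	66	0.03
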