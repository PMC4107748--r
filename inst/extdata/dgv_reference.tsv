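cnv_id	loss_freq	gain_freq	source_n
esv27061	NA	5.8	NA
esv2757747	NA	0.8	NA
dgv1306e1	0	0	NA
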