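cnv_id	snp_id	chrom	start	end	assay_id
esv27061	rs2932538	chr1	112,692,629	113,246,263	Hs01327571
esv2757747	rs2932538	chr1	113,157,135	116,741,372	Hs01327571
nsv483076	rs7129220	chr11	10,193,294	10,352,897	Hs04399968
dgv976e1	rs17608766	chr17	44,083,914	45,277,333	Hs00313538
esv2656635	rs17608766	chr17	44,281,452	45,168,501	Hs00313538
nsv908562	rs17608766	chr17	44,828,931	45,102,413	Hs00313538
dgv986e1	rs17608766	chr17	44,971,360	45,277,333	Hs00313538
dgv1306e1	rs1327235	chr20	10,892,138	11,116,725	Hs03126928
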