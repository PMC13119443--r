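segment	chrom	start	end
exon1	chr22	42526741	42526883
exon2	chr22	42526436	42526613
exon3	chr22	42525739	42525911
exon4	chr22	42525035	42525187
exon5	chr22	42524785	42524946
exon6	chr22	42524175	42524352
exon7	chr22	42523805	42523985
exon8	chr22	42523449	42523636
exon9	chr22	42522513	42522754
upstream_homolog	chr22	42526900	42528100
paralog_CYP2D7	chr22	42536213	42542413
paralog_CYP2D8P	chr22	42547600	42551600
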