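pair_id,chrom_a,pos_a,chrom_b,pos_b,signal_rep1,signal_rep2
1,chrXV,152000,chrXV,478000,42.1,38.5
2,chrXV,232000,chrXV,412000,61.7,57.9
3,chrXV,152000,chrXV,305000,24.3,22.1
4,chrXII,120000,chrXII,780000,3.1,2.7
5,chrVII,420000,chrXIII,310000,1.9,1.6
6,chrIV,510000,chrX,260000,1.2,1.0
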