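f6fa20cb311e6af921d47b83f7f23e85 synthetic_species_tree.nwk
2682c43c25f36d58519e89992019e029 synthetic_freqs.tsv
0166c50db28eb2230714fa1718789da1 synthetic_reference.fasta
0cf4863b0970a6d301075c4c8dffcbec synthetic_sp1.fasta
54265e2bf649f2b7615081d3dd314ec9 synthetic_sp2.fasta
70987d3bd636ecb7c03a54b2a8f62854 synthetic_sp3.fasta
90359aaa3c1fec7106aac19d8ce700ca synthetic_sp4.fasta
9212261951b1a7e6b990d6dcccdb7c23 synthetic_sp5.fasta
71211d1aae09e1d67c1819532f40ea3c synthetic_sp6.fasta
2990d7bb5a77411f890ee3c633e833ee synthetic_sp7.fasta
573550e0ea81a78835ff03e254921a4a synthetic_null_values.txt
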