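>synthetic_rRNA_fragment_1
AGCTTAACTACGCATACTGCCTCTTGAGTGCCTTCC
>synthetic_rRNA_fragment_2
AGGGTCCGGTGGGCAACTATCCTGCACCACTACGATCCCT
>synthetic_rRNA_fragment_3
AGCAGCCCACGACCCCAAGCGGGGTCGGCTGC
>synthetic_rRNA_fragment_4
AAAAGCGTAGGACGTTTGTACCGCGGGTAGATATCCACTTCAGTGCGCGCGTGATCCAAA
>synthetic_rRNA_fragment_5
TCCTATCCTTCGGGGGGTACGGCTGTAA
>synthetic_rRNA_fragment_6
GATGCCGAGCCGATTGATGTCTGCTCCAGGAGACTACATGGGTGC
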