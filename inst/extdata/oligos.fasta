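>AKN1 canonical 12RSS substrate, top strand
GATCAGCTGATAGCTACCACAGTGCTACAGACTGGAACAAAAACCCTGCT
>AKN2 canonical 12RSS substrate, bottom strand
TAGCAGGGTTTTTGTTCCAGTCTGTAGCACTGTGGTAGCTATCAGCTGAT
>AP92 CAMK2D fragile region, top strand
TCGACAGGGTTTAAATGAAGCACAGCAAAGAAATTAGAGCTACAAAAACATTGTG
>AP93 CAMK2D fragile region, bottom strand
TCGACACAATGTTTTTGTAGCTCTAATTTCTTTGCTGTGCTTCATTTAAACCCTG
>AP94 RNF38-MELK fragile region, top strand
GATCCGCTGTGAGCTGAGATCACTCCATTGCACTCCAGCTGGTGCAACAGAGCAAAACTCCATCG
>AP95 RNF38-MELK fragile region, bottom strand
GATCCGATGGAGTTTTGCTCTGTTGCACCAGCTGGAGTGCAATGGAGTGATCTCAGCTCACAGCG
>AP96 AMY1B fragile region, top strand
TCGACTAGTGTTCTGTTAAGCACAGAACAATTTTACAGAACACAAGCATCAGACAAGTCTACTCG
>AP97 AMY1B fragile region, bottom strand
TCGACGAGTAGACTTGTCTGATGCTTGTGTTCTGTAAAATTGTTCTGTGCTTAACAGAACACTAG
>AP98 DIPK1A fragile region, top strand
GATCCAAAGAACTCTACTTTCACCCTAATTAATACAAAAGGAGCCAATAATAGGAAAGACAAAATG
>AP99 DIPK1A fragile region, bottom strand
GATCCATTTTGTCTTTCCTATTATTGGCTCCTTTTGTATTAATTAGGGTGAAAGTAGAGTTCTTTG
>AP100 RN7SKP123-MTF2 fragile region, top strand
TCGACAAACTTGGGACAGCCCACAGGTAGGAAGCAAGAGAAAGAAAAATAGAAG
>AP101 RN7SKP123-MTF2 fragile region, bottom strand
TCGACTTCTATTTTTCTTTCTCTTGCTTCCTACCTGTGGGCTGTCCCAAGTTTG
>DG13 negative control without cryptic RSS, top strand
GATCCCTCTAGACCGGTACTACTCGAGCCACACCCGCCCGCTGCACCCTCCTCCC
>DG14 negative control without cryptic RSS, bottom strand
GGGCGGGAGGAGGGTGCAGCGGGCGGGTGTGGCTCGAGTAGTACCGGTCTAGAGG
>DG27 negative control without cryptic RSS, top strand
GATCCCTCTAGACCGGTACTACTCGAGCGGCCCGGCGCTGCCAGCGCGGGCTCGG
>DG28 negative control without cryptic RSS, bottom strand
GGGCCCGAGCCCGCGCTGGCAGCGCCGGGCCGCTCGAGTAGTACCGGTCTAGAGG
>MS20 pull-down control without heptamer/nonamer, top strand
TTTTTTTTTTGACCATTGGCGATCTCAGCGTACGGACGACTTCGGATGACTTTTTTTTTT
>MS21 pull-down control without heptamer/nonamer, bottom strand
GTCATCCGAAGTCGTCCGTACGCTGAGATCGCCAATGGTC
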