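>spA01_1
TCGCATTTGCACAAGACCTCTGGGCTACCCAACAGAGCACGCCCCTTTACACTCGTCTGGGATCTCAGGGAAACAAAGTCCATCAGGTTCATATTCTACTTCTATCCAGATCTCTATCCCGACGGTAAGCTCTGCAGGACCTGTTCTGTGCCTCGTCTGTTTAGCAATTGCCCAATCCTGTTGAAGCTCAAGAGACACGCAGTCATTGAGATGACCGCGTTTGGATACCTCCAACATAACAGTCTGCCGAGAGAGCTTGTAAAC
>spA01_3
TTGCATTTGCACAAGACCTCCGGGCTACCCAACAGAGCACGCCCCTTAACACTCGTCTGGGATCTGAGGGAAACAAAGTCGATCAGGTTCATATTCTACTTCTATCCAGATCTCTATCCCGACGGTAAGCTCTGCAGGACCTGTTCTGTGCCTCGTCTGTTTAGCAATTGCCCAATCCTGTTGAAGCTCAAGAGACAGGCAGTCATTGAGATCACTGCGTTTGGATACCTCCAGCATAACAGTCTGCCGAGAGAGCTTGTAAAC
>spA01_2
TCGCATTTGCACAAGACCTCTGGGCTACCCAACAGAGCAAGCCCCTTAACGCTCGTCTGGGATCTCAGGGAGACAAAGTCCATCGGGATCATGTTCTACTTCTATCCAAATCTATATCCCGACGGGCAGCTGTGTAGGACCTGTTCTGCGCCTCTTCTGTTTAGCAAGTGCCCAATCCTGTTGAAGCTCAAGAGACACGCAGTCTGTGAAATAACCGCGTTTGGATACCTCCAGCATACGACTCTGCCGAGAGAGCTTGTAAAC
>spA04_3
TCGCATGGGCCGAATACCTCTGAGCTGCTGAATAGGAGAAGCCTCTTAACGCTCCCCAAGGACCTACGTGAAGCGAAGTCTACCAGGTTGACATCCTACTTCTATCCAAATCTGTATCCCGAGAGTAAGCTCTGCAGGACCTATTTCGTACTTCTTTTGTCTGGCGTTTGCCCAATCCTGTTTAAGCTGAAGAGACACGCAGAAAGTGTAATAACCTCGGGTGGATACCTGCAACATACGAGTCTGCCGAAAGAGATTGTAAAG
>spA04_2
CCGCATGGGCCGAAGACCTCTGAGCTGCTGAATAGGAGACGCCTCTTAACGCTCCCCAAGGGCCTACGGGAAGCGGAATCTACCAGGTTGACATCCTACGTCTATCCAAATCTGTATCCCGAGGGTAAGCTCTGCAGGACCTATTTCGTACTTCTTTTGTCTGGCGTTTGCCCAATCTTGTTTAAGCTGAGGAGACACGCAGAAAGTGTAATGACCTCGAATGGATACCTGCACCATACGACTCTGCCGAAAGAGTTTGTAAAG
>spA04_1
CCGCATGGGCTGAAGACCTCTGAGCTGCTGAATAGGAGACGCCTCTTAACGCTCCCCAAGGACCTACGGGAAGCGAAGTCTACCAGGTTGACATCCTACGTCTATCCAAATCTGTATCCCGAGAGTAAGCTCTACAGGACCTATTTCGTACCTCTTTTGTCTGGCGTTTGCCCAATCCTGTTTATGCTGAAGAGACACGCAGAAAGTGTAATATCCTCGGATGGATACCTACAACATACGACTTTGCCGAATGAGATTGTAAAG
>spA02_3
TCGCATGGGCAGAAGACCTCTGAGCTGTTGAGTAGGAGGCGCCTCTTAACGCTCCCCAAGGAGCTACGGGAGGTGAAGTCTACCAGGTTGACATTCTGCGTCTATCCAACTCTGGATCCCGAGAGTAAGCTCTGCAGGACCTATTCCGTACTTCTTTTGTCTGAGATTTGCGCAATCGTGTTTAAGCTGAAGGGACACGCAGAAAGCGTAATAACCTCGGATGGACACCTGCAACATACGACTTTGGCGAAAGAGATTGTAAAG
>spA02_1
TCGCATGGGCAGAAGACCTCTGAGCTGCTGAGTAGGAGGCGCCTCTTAACGCTCCCCAAGGAGCTACGGGAGGTGAAGTCTACCAGGTTGACATTCTGCGTCTATCCAACTCTGGATCCCGAGAGTAAGCTCTGCAGGACCTATTCCGTACTTCTTTTGTCTGAGATTTGCGCAATCGTGTTTAAGCTGAAGGGACACGCAGAAAGCGTAATAACCTCGGATGGACACCTGCAACATACGACTTTGGCGAAAGAGATTGTAAAG
>spA02_2
TCGCATGGGCAGCAGACCTCTGAGCTGCTGAATAGGAGACGCCTCTTAACGCTCCCCAAGGACCTACTGGAGGCGAAGTCTACCAGGTTGACATCCTACGTCTATCCCACTCTGTATCACGAGAGTAAGCACTGCAGGACCTATTCCGAACTTCTTTTGTCTGGCATTCGCCCAATCCTGTTTAAGCTGAAGAGACACGCAGAAAGGGTAATAACCTCGGATGGATACCTGGAACATTCGACTTTGGCGAAAGAGATTGTAAAG
>spA03_3
TCGCATGGGCAGAAGACCTCTGAGCTGCTGAAGAGGGGACGCCTCGTAACGCTCCGCAAGGATCTACGGGAATCGAAGTCTACAAGGTTGACATCCTACGTCTATCCAAATCTGTATCCCGAGAATAAGCTCTGCAGGACCTATTCCGTACTTCTTTTGTCTGGCAATTGCCCAATCCTGTTTAACCTGAAGAGACACGCAGAAAGTGTAGTAACCTCGGATGGATACCTGCAACATAAGACTTTGCCGAAAGAGATTGTAAAC
>spA03_2
TCGCATGGGCAGAAGACCTCTGAGCTGCTGAAGAGGGGACGCCTCGTAACGCTCCGCAAGGATCTACGGGAATCGAAGTCTACAAGGTTGACATCCTACGTCTATACAAATCTGTATCCCGAGAATAAGCTCTGCAGGACCTATTCCGTCCTTCTTTTGTCTGGCAATTGCCCAATCCTGTTTAACCTGAAGAGACACGCAGAAAGTGTAATAACCTCGGATGGATACCTGCAACATAAGACTTTGCCGAAAGAGATTGTAAAC
>spA03_1
CCGCATGGGCAGAAGACCTCTGAGATGCTGAAGAGGAGGCGCCTCTTGACGCTCCCCAAGGATCTACCCGAAGCGAAGTCTACCAGGTTGACATCCTACGTCTATCCAAATCTGTATCCTGAGAATAAGCTCTGCAGGACCTATTCCGTACTTCATTTGTCTGGCAATTGCCCAATCCTGTTTAAGCTGAAGAGACACGCCGAAGGTATAATAACCGCGGATGGATACCTGCAACACACGACTTTGCCGAAAGAGATTGTGAAG
>spB01_2
TTGGACAGGGCGCACACCCCTGTGCTCATAGCCACCACACGCCTGCAAGAGCAACTCGGGTATCTACGGGAGACCTCGTTGTTCCGCTTAACATCCTACTTATATTCAAATCTGCACCCGGACACCAAATTCTGCACACCTTATGCTGTCCCGCTTATGGCCACCATTGGCCGTGTCCTCTTTAAGCCGTACACAGACTCAGTACCGCAGATGGGCGCCCGCGTATGCCCCCAAAATGCCACGCCCCTGAGAGGGAATGCAAAG
>spB01_1
TTGGACAGGGCGCAGACCCCTGTGCTCATAGCCACCACACGCCTGCAAGAGCAACTCGGGTATCTACGGGAGACCACGTTGTTCCGCTTAACATCCTACTTATATTCCAATCTGCACCCGGACACCAAATTCTGCACACCTTATGCTGTCCCACTTATGGCCACCATTGGCCGTGTCCTCTTTAAGCCGTACACAGACTCAGTACCGCAGATGGGCGCCCGCGTATGCCCCCAAAATGCCACGCCCCTGAGAGGGAATGCAAAG
>spB01_3
TTGGAAAGGGCGCAGACCCCTGTGCTCATAGCCACCACACGCCTGCAAGAGCAACTCGGGTATCTACGGGAGACCACGTTCTTCGGCTTGACATCCTACTTATATTCCAATCTGCACCCGGACACCAAATTCTGCACACCTTATTCTGTCCCGATTATGGCCACCATTGACCGTGTCCTCTTTAAGCCGTACACCGACCCAGTACCGCAGATGGGCGCCCGCGTATGCCCCCAAAATGACACGACCCTGAGAGGGAATGCGAAG
>spB02_1
TGCCACGGGATGCAGACTCCTGGGCGGATAGCCATGACACGGTTGCTAAACCACGTCGATGATTTAAGCGAGACGACCTTGTTGGGCTCGAGATCCCACTTATATTCCAATCTGTCTCTGAACACCGAAATCCGTATGACTTATTCCTTCCCGCTTATAGCTACCATTGGCCGTGTCCTGTTTACGCTATACACAGGCACAGTACGGCTGATGGCCGCGCACGTATGCCTCCAAAATGCCATGCCCTTGAGAACGATTGCAAAG
>spB02_3
TGCCACGGGATGCAGACTCCTGGGCGGATAGCCATGACACGCTTGCTAAACCACGTCGATGATTTAAGCGAGACGACCTTGTTGGGCTCGAGATCCCACTTCTATTCCAATCTGTCTCTGAACACCGAAATCCGTATAACTTATTCCTTCCCGCTTACAGCTACCATTGGCCGTGTCCTGTTTACGCTATACACAGGCACAGTACGGCTGATGGCCGCGCACGTATTCCTCCAAAATGCCATGCCTTTGAGAACGATTGCAAAG
>spB02_2
AACCACGGGATGCAGACTCCTGGGCGGATAGCCATGACACGGTTGCTAAACCACGTCGATGCTTTACGCGAGACGACCTTATTGGGCTCGAGATCCTACTTATATTCCAATCTGTATCTCAACACCAAATTCCGTATAACTTATTCCGTCCCGCTTATAGCTACCATTGGCCGTGTCCTGTTGACGTTGTACACAGACACAGTGCGGCTGATGGCCGCGCACGTATGCCTCCAAAATGCCACGCCTCTGCGAACGATTGCAAAG
>spB03_1
TTCCACGGGATGCAGACTCCTGGGCGGATCGTCACGACACGGATGCTAAACCACGTCGATGATTTACGCGAGACGACCTTGTTGGGCTCGAGATCCTACTCATATTCCAATCTGTACCTGAACACCAAGTTCCGTATAACTTATTTCGTCACGCTTATAGCTACCATTGGCCGTGTGCTGTTTACGCTGTACACAGACACAGTACGGCTGATGGCCGCGCACGTATGCCTCCAAAATGCCACGCCTCTGAAAACGATTGTAAAG
>spB03_2
TTCCACGGGATGCACACTCCTGGGCGGATCGCCACGACACGGTTGCTAAACCACGTCGATGATTTACGCGAGACGACCTTGTTGGGCTCGAGATCCTACTTATATTCCAATCTGTATGTGAACACCAAATCCCGTATAACTAATCTCGTCCCGCTTATAGCTTCCATTGGCCGTGTCCTGTTTACGCTGTACACAGACACGGGACGGCTGATCGGCGCGCACGTATGCCTCCAAAATGCCACGCCTCCGAAAACGAATGCAAAG
>spB03_3
CACCACGGGATGAAGACTCCTGGGCCGATAGCCACGACACGGTTGCTGGACCACGTCGATGATTTACGCGAGACGACCTTGTTGGGCTCGAGATCCTACTTAAATTCCAATCTGTATCTGAACACCAAATTCCGTATAACTTATTCCGTCCCGCTTATAGCTACCATTGGCCGTGTCCTGTTTACGCTGTACACAGACACAATACGGCTGATGGCCGCGCACGTATGGCTCCAAAATGCGACGCCTCTGAAAACGATTGCAAAG
>spB04_1
TTGCACGGGGCGCAGACTCCTGAGCTGATAGCCACGACACGGTTGCTAAACCACGTCGATGGTTTACGCGAGACGACGTTGTTGGGCTCGAGATCCTACTTATATTTCTATCTGTATCTGGACACGAAATTCTGGACACCTTATTCTGTCCCGCTTATAGCCACCATTTGCCTTGTCCTGTTTTCGCTGCACACAGACACCGTACGGCTGATCGCCGCCCGCCTATGCCTCCAACATGCCCCGCCTCTGAGAGCGGTGTCAAGG
>spB04_3
TTGCACGGGGCGCAGACTCCTGAGCTGATGGCCACGACACGGTTGTTAAACCACGTCGATGGTTTACGCGAGACGACGTTGTTGGGCTCGAGATCCTACCTATATTTCTATCTGTATCTGGACACGAAATTCTGTACAACTTATTCTGTCCCGCTTATAGCCACCATTTGCCTTGTCCTGTTTACGCTGCACACAGACACCGTACGGCTGATCGCCGCGCGCCTATGCCTCCAACATGCCCCGCCTCTGAGAGCGGTGTCAAAG
>spB04_2
TTGCACGGGGCGCAGACTCCTGAGCTGATGGCCACGGCACGGTTACTAAACCACGTCGATGCTTTACGCGAGACGACGTTGTTGGGCCCGAGATCCTACTTATATTTCTACCTCTATCTGGACACGAAATTCTGTACAACTTATTCGGTCCCGCTTATCGCCACCATTTGCCTTGTCCTGCTTACGCAGCACACAGACACAGTACGGCTGATCGCCGACCGCCTATGCCTCCAACATGCCCCGCCTCTCAGGGGGGTTTCAAAG
>outgroup_1
TCGCACCGGACAAAGACCTATGACCTCTTAGAAGCCTCGCGTTTCCTAAATGTCGTCAAGGAGCTAAGGAAGATGGCGTCAATCAGATCGATATCACACACGAATCCCAATACGCATCTAGACGGAGAACTCTGCAGAACCTTTTCGCTGCTTCTCCTTCCTATGATTGACCCTAACATCCTTATGCTGAAGAAGGGCGCGGTATTGGTAAGCAGCCCGCGAGAGTGCGGCCGGAACACCTTGTTGTTGAGAGAGATTGTGCAG
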