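>synthetic-1000-1 synthetic stand-in substrate (1033 nt: GGG + 1000 nt diverse + 30 nt poly(A))
GGGUAGCCUCUCGCCGGCUAGAAGAGGGGGAGUCCUCACUCUGAGAAUGGUAAGGUAAUUGCAGAUGAACUAGCAUCGAU
GGCCGGUCUAUGGGUCUGAGUUUCCUCGUGACAGUAAAACUCGAAACCUGUUCAUGCUCUCGUUGAUUGAAGGGGUGAAU
UUCUUGGAGUCGCCGCGUCAACUUUGGUUCAGCGCUGUCUGGGGAGAGAUAACCCAGAUGUGGAGAAAGCCGGCGGUGGU
GCCAGCUAUGUUGAUAUUGUCUAGUGGUAACUUCGCUGUCACGGGCCCCAGUGCCUAAAUACGCGAUCAUAAACCAACUG
CCGGUAUCUAUCCCCGAAGUCUAGGCUGGGGAGAGCAGACCCGCCUGAGAAACGUUUACAUCCAUUGGAAUUACCUAGAU
UGCGCUCCAGUGCACCGGGCCCUGACAACUUCUUCUAAGAUUCGGAACUCCUUUCGCUGGUUGUCCUAGGUUCUGAGCGA
AGGUGGACAAUAUUCACCAUUUGGAUUGUUCGGGUAGGACCGGUUCAAUCUGGGGGCUUUAACUAGGCGGGAAGACGAUA
CCGGGAAUGGUGCAGGCCCCCCGGCAUACAAAUUGUCAGGCAUGUAGGGACCAGCUUCGCGGCGUAACAAAAUACUUGUC
AUGUGAUGCCUUGCGAUCUGUUGAUGUGACGUGCUGUUGGUUCGUUCAUCUCAAGUUUCGCUGUGAGCUUCCUAAUGCGU
CCAACUUCGCAUCCCCCUGCUUCUCUUCGACUUGCUCGCAUCCACUGGUCUCUUACCAUGGUCUCUAGUCUCCCGUCCCG
AGAAGUAGGAAGAAAGCCUUGGGUCUACUCACCUAUUACUGCUCCAAAUCCGCUGCCCUCAGGCUGUAUUACAUACACCU
AGUGCACAGAGACAGCAUUAUAUGCUUCAUCUAGAGGUUUAUACAACGGAGUCAGCGCUCAAAGACCGACCUCCUAUUAC
AAUACGGUAUAAGGGAGAAACGGUACCUGGGCCUGUAAGAUGUAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>synthetic-1000-2 synthetic stand-in substrate (1033 nt: GGG + 1000 nt diverse + 30 nt poly(A))
GGGUGAGAAUACUUACGGCAUACGACCAGGUCUAAUUUUAAGUUGCUACAGCGUCACGCGUCUGCCUUCAGGGCGUCCAC
AUAGCAUUUUGUAGUCUAAUAGCCACAUAGCGCCUAACGGGAAAGGGCGGGGAUGCAACCAACUUAUACGUGAGUGGGGU
CUCACAGCUCGAUAUAACACUGAUGGCGUAGGAGUGAACAAAGUCGCCGACUUACUGCUUCUAUGGUUUCCCAAUAGGAC
CUACGGGACGCUGUUCGCUAACCGUGCCGGCCUCUGCCAGGGCUUACGCUUCUUGCUACCAAAUUUAAGUUACCCGUAGG
CCUCGUAAGCACGAGGUCGAAAUUACACAACCCUAUAGGGAGGGACAGGUGGAGUGUCGUUUCACUUUCACAAGUCAGAG
UUGUUCAUACCCGGUAUUUCACUAGACGGGGUUGUUCGGUGCGAUGACCAUGGAGUCAUGCCAAAUUUAGCAAUUGUCAU
GGCGAACGCCGCCGGGUAGUACUAGUCCCUGUUUGCUCAAGUGGGUCUACACGAGCUAAGUGUGUUCCGAAUAAGUAUUU
GUCCCGGGUAUUUACAGAAAUGUCGUCGUAUCGCUUUGAGUUUGCAUAUACGUGUUUAAGCUCAAACCAUUACCCCUCAG
UGGAUUGUUUUGUCGUAGACACUGAAAAACUCUCUUGGCAAUCAUGAAUUACAGGUAAAGGCUUCCUUCUAAUCGUCAUC
GCCUUCGAGGAUUUUCGUCACAAAGCGAGGCACCGCCGAACGUGGAGACAGUAGCUGAGCCAAGGUAGAAAAUAAGUGUC
UUUGCCACUCUACCUGCUUAAAUCACGCCUUAAACACACAUGGACGAUAAGCGGUACUAGACUCGUUGAGAUCACAGUAU
AUCUCGAGAGGUCGUUGCACAGGCUUGGAAUUAUAUCAAAAGUAUCCAUGGAACCGGAGAUGUCGGCUAGAGUAAAGGUG
UGGGGCCGUGUUGACACGGAAAAACAAAUACGGGCGUUACGACAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>synthetic-1000-3 synthetic stand-in substrate (1033 nt: GGG + 1000 nt diverse + 30 nt poly(A))
GGGGGGGGAUUAAUAGGAGCCCUUAACUGGAGACCUACGACACCGCGGCGCAGCCUGCGGUCCGAGGGGGUUCUAAAUAA
UCAGAAAUGUCUUCAUAACCGGGCCUAUGCGCUUUGGAGCGACUUAUUUAAUUGCCACAUCCAGAGCUGACUAUGGUCGG
GUCUAGCCUUUAGUAAGUCACAGCAUCCGGCACAUAAAAUACUGGUGGGGCCCGACUUAUAUGCGGUGGAAAGAAUGUUC
CCUGUGUAUUUAAAACGGGCAGAAUACGUGUUCCUCUAGGCACCUGUACGCUCGAAGGGGUAGCAUCUGAUGCCAGUGCG
AACCUACACCGGUAUUAAAAAUUUGGAGUAUUAUACACGUCGAGUCUUAAUGCCCGUAUCGACGACCUUUCGGUCCGAAG
GUCCAUGGCAGCACCUUUCGGUAGUACCGGAGGUCUGUGGGAGUUCCCCUCGGAUUAAAUAAAUGGGACGCUUUGAGAAC
UUCAAAGAAACCGAUUAUGGGAUGCAACAGUAUAUAGACAACUGGGGUUGCCAUAGGACUUUGUACCCGUAUACAAGGUC
GAAGCAUCCACCUUGCACAGCCUCCUACCGCAUUAAGGCUCGAACCCGCCUCGGACGGACGGCAAGAAGAAUGUAGCGUU
UAUCAGAAUUAUCCACCUCGCGGUGCAGAUUAACUUCCAAAGUCUGAUCACUGACUGAGGAGAUAUGGUGACAGAUCCCC
CUCGUCAGUAACCGGUAUCGGUGGAAGUAGUUUGUUGGGACCGAGGUAUGGAGGUACUGUUUAUGGAUCAUGUGAUUGCA
AGAACACUUCACGGAGUGGCUGUCUGAUUGGAAAAAGGAUGCCUACUUAAGAUAGCGGGGGGUCAAAACUAUGAGCGAUG
CGCACCGGAACUCUUACGGGGUCGUGUACGUUAAUGGAGCGGUUACAUUUAUUAAUUAUGACUUUGUUCACAGAGCUACU
UGUGUCGUUCCUGGGCAUGACUCCGGAACCAGUAAAGCAACUUAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>synthetic-1000-4 synthetic stand-in substrate (1033 nt: GGG + 1000 nt diverse + 30 nt poly(A))
GGGGACCAAUGCCCGUCAGCCUUCGCCUGUUGCUACAAUUAAGUCCGUCGCGGUAAGGGACCGAAUACUAGUGAUAACAU
CCUACGGGGAGUGGGACAGUAACUCGGAAGCAACGUGCAAGCAACGAUGUACGUAUUCGGUACCUAAAGCAGUGGCACGC
AAAUCUUUUCCUCUGUACUGAGAUCCUAGAGCCGAGUUCGAGGCCAGCAGUUGAUGUUCAAACAGCGUCGUCUAACAACG
AGGCUGGAAUGUACAUGUUUCAAAAAGAGCCGACAGUUUCACCUCUAUUCUCAGGAACGCAGCAAACUAAGUAUUCGAUG
AGUGUUAAUCACACCCAGGAUCCCCUGUUGCGGAAGCCUGGCGCAAGGGCCAGGUAAUGGAUACGUGAAUCGCAUCCGAG
GCGCUGCCAGUCCGUUCGAAAGUGGCCAUGAGUGGCAUCAGGCAAGCCUCGUAGUCUGCGCAUCCCGUGCCGCGCCACCC
CUGGCUCAGAUAGGCGCAACGCAUAAUGUGAUGUGGUACAUCUACACCGGUGAUUGCAUACAGACAUCUCACGCAAAUCG
CAGAUGCAUCGUGUCAGAUAUAACCUGUAGCCACCACCCUACAGUGAUAUAAUAUCACUCUCAUGACUGAUGCAUUCCUU
AUCGGCAGAUACCAUAUUAGGUAUUCGUGUUGGCCGUCCACGCUACGUGCAGCUCCGUUUCAAAGGCUCUCACCGCGUUC
GGCUGAACCUUAGUCAAUGCCACAACACUAAUCGCGCUCGCGCGGUGGCCAAACAGCAGGUUUUUGUUAAGGAUAUUAGC
GCGAGAUUUUUUCUUUUCGACUGUCUUCGAUAGCUCCAUUUCACUUGCUUUCUUGCAGACAGCCCUGGCUCCUAGAUUGC
CCUGCGCUGUCGUUGCCAGCUGUUCCGUGGCUGGGGUAAGUCCGAGCUCUCCUUCGCCGUCCAGGAAUACGAACGGCUCU
CGUUCACUAUGGCCCAGACAUUAGGUACACGAUUGUUACCCCGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>synthetic-1000-5 synthetic stand-in substrate (1033 nt: GGG + 1000 nt diverse + 30 nt poly(A))
GGGAGGCUCCGUCACGAGUGGUAUAGCAAGUGGGACGAACCGUAGCUCGUGUCCAAACAUCGUUCGUACUUAACCCAGGU
GAUUGAGUAACGAAACCCGCACAAGGCGGGAUAUCGUCGUAUUGACGGCUUCCAGUAACGGUGCGGAUUCCUGGACGUUG
GUGGCGGUGACAGCACUCGAUGGCUACCUUAGCGUCCCGCAGGUAAACCUCGCUACGCGCUCCCUAACUCUAAACUCCCU
CUCGUAGUUGCGCCGUCCGGAUGCCGAGACACGUAUAUUUGACCGUGGCGCGCGUUCCUCGUAUCUCUAACAGUAAAAUU
CUUACACAUGCGUACACCAAACACAACCUACGUUUCUGCUGCUUCCCGAUCAUCGGUGAACACAUGGGACCAUGCACUCU
ACGCGGGGACGCCCCCGACCGGACCUGGACUAUACGUAGAGCUCGUUAGCAUGCUUUAAAGCUCUGGAGCAGAUGGCCGC
CAAUGUUAUGGUGGACUACACCUGUAACGUGGAGACGUCGCUAGGGGGCACCACCGGAACAAGAGAAAUGGCGGCGGCCC
UCAACCCCACCGUAGAUUGAUGAGAAGGCGUUUCUAAUACUGAACUCUUACAUAAGUAUCACACUUAGUUAGAUGUCGUU
UUGUAUAUCUCAGCUUCGGUUCGAAUAGCAUCUGCGUGGAUGGAAAUAUCAAGGCCGGGUUACCGUUGAUGCGACGCUGA
CGAGCUAGCUACAAGACCUGCAGAUGAAAUUCCACGGCAUGGGCGGUGCUCUAUUGCUCCAAUCUCUUACACAACUUCUC
AGCAGUGUAGUCGCUGAAGACUUGGGUCGGGUACCGGUCAACACAAGUGGGUUGGCUUCCCCCUGCGGUCGUCGUAUGCG
GCAUAGCAGAGUGCGUCCAAAGCCCUCGUGAGAUCCGUAAGGCAGACUCUGCUCGACUAUACACCUUGUACUCACUGUCA
GUAAGACUCCGAAUGGGUCACAGAGCGUCCUAAUGAUCGAGCGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
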