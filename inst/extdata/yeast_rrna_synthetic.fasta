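>18S synthetic stand-in
UACGUGUAAAGGCCUCUUAGGCCACUGGGGGGGCCCUUUCAGCUAUAAGGCACCGAUAUGAACCUCGAAG
ACGAGAGUGUCACAUCAACGGGUGCGAUCAGGUUGUCGUCACAUUGAGAACGUAUAAGCCUCAGCAACCU
CAUUUGUGGGGAUGGGGUGACUCCCGAGCUACUCGAAAAUUGUUCGCCUCCCGUACGACGGCUACGCGGA
UUAGUGACGCAGCUCAACGGUAGGAUGUCCUUUCGUAUUAGCCUGAUUCAAAAGUACGGCUUCUUAGCGU
UGAUUUUCAGGCUCCGGAAAGCCCAAAGUCUCUUCGUUCACUCGGACACAUGAGCUAUAGAGAAUUCGUC
AAAGUGCAGCGAAGGUAAACCAAGUUAUGAGGGCUGGCUAGGAACACCCCGAGUCUUUUAGGUCCUGGAA
CUGGGGACGCCUUCAAGUGUAUAGGCCAGCGCCUACUGUACAAGGAGGAAGCCCCUGAAUAUUAGGACGU
UAGUCAGAGCAGUGUAGAUAGAAAAAUGAAUACUCACCGGCCAAAACCUUCAUCACCAGGCGCCGCUUUA
CUUUUACUAUUUUGGAAAUGGCUUCUGGUGAUGCGGGCUGAGCUACUUGGGAAUUUUGACCGAAUGACUA
AUACUAAAUAGUUAACUCUUCUGAGAUGCAUCGGGCCCAAUGGUAAAGAUCUGGGCCUCCCUACGUCACG
UGAGAACGAAAAUUUGUGUGAGCAGGCGAUUAUGCAUGCGGACAAGUCCUGUCAUCAUUAGACUCUGCCG
CCGAUAUAUAGCCCUGUGUCUAUUGCGUGCUCUCGCUGUGGACCGGACUAACAUACCUGUCCCCGCCAGG
GUCCGCCCUCGGAGCGUGUACCUCCACGCACCACCACCACGGUGUAGAUCAGUCUGGAUCUAGUUGUACC
CCGCUCGCGCAAAACCGAUCUUCGAGACCUAGUCCGCCAUUUGGGGUAUUUACUGAUAAGGUCAUGGGCA
GCUACGGAGCCUGUUCGGUAGUCACCGGGCUGUUCUAAGAAAACGGCGGUCAACUUAUAAAGAGCUGGCC
AAUAUGGAUUGCGAUCGUUUCACUUGAGGCAGCACACCGAUCGGCUAAAGUACGAUCUCCCUAUGACUUA
AAUAGGGACCACGCGAUGAUGAGCAUGAUUGCUCGACCGCGAGUGCCACUAAGGGGAUGGCAAGGGCGGG
UAGAAGUCAAGCAGUAAGUCGUUGUUACAGCGAGAUUCUGUCUACAACCGUGUGUGAAGAUCCUAAGGCU
CCACGGACUUGGGAAUAGACGCUUCUCUGUGUUGGCUUGCUCAAGGGGAACAAGUCGCGGGACCAUUAGU
UUUUAACUCCCCCCCAAGCGCGACAUGACUAGUAGUGCGUUGUAUUAUACUAUAGUCUACAUGAGCAAUG
UAGUCGCGGGCAUUUCCCUCUGGUUCACUCCAUACGGCUGGGUAAUACGGCGGUUCGCGUUCGAUGGUUG
GCUCGCUUUGCGCCCCUCCGACGCGCGUUCGCUGUAAGUCCCACGCCACGCACUCCAAGCGUUCGAUCAA
GCCCUUUGGUACGCCGUUGUCGCGAUUACCAGACUAAAGAAUCACAGCGCAUACGAAUCCUAUAGAUACC
CGCCGAAGGAGCAGCCUUGUCUUCUCCGCUGGUCAUUCAGGUGCAUCAGGUUUAUAAGAACACCACUGUC
CUGUCCGUUUGCGAUACGCUGUCUCGAACGACACGGAGACAAAGAUGUAGGCUAGGUCGACUUAGCUCGC
CGUUUGCGUCAUUUCUAUGAUUCUAAUUACCAUGUCGUGUUCGAUGAUUC
>25S synthetic stand-in
AUCAGCUGAACAGCCUUUUAAGCGUUAUUUACUCCCGUCUCUGCGUAUGUGCUUCGCGAGACCGGGGAUU
CAACUACGGAUGAGUCCGUAAGUUUGGUGGAUGAGGGCCUCAGACCUAUGUAGGAUUAGCCGGGACCAGC
UUGUGUUUUCACACUGUUGCCAACGACACUAAGCGUAGGUCUUCACAAAUGGAGCGGAGAGCCGACUAAG
GAGAAUGGUAGGCUGGCCUGCCUAUCGAUGCCACCUGAGCCCCGUUUGCGGACAUCGCGGGUGAACCCAG
ACACCUACAUGUUCUAACGAGGAAACGAGUAUUUAGAAACAAGGAGUAGUUAACUGGCGCAUUGCGAACA
UUCAAUGUGAGAAGGCCCAUGCUUGUAUGAAAGGUGCUAUACCUUUUGUGGGGUGCACUCCGGGAGACCC
UCGUGACAAGAUCGGGCUCCACUGAGCUAGGGCGUCGCUCCAUAUAUAUACGCAAAUGCUGUUCCGUAAG
CCUGGCGCGUAGAAGGUAUUAAAUGCGUUGGAACUGUGGGCCUAACCACCGUACUGUUCAAUUGGUUUGC
UUCCCUCUCCCUUACGUCUUGUAUUUGAAGCUCUAGCAUCAAUGCAACGUCCGGGACAACGGUGAAAUAC
UGUCUUGCGUUACCGUCAUAUUCCACAGUGGCACCCUCCCAAUAACUUUAGAGCUGUCCACACAUAGAUC
CGGAGAAUUACCUAUAAGGAAAGCUAUGGUAUUCAAGUUAAGAACGUCUCGAAAGCCGACGCGGUUUAUC
GAAGUUCGCCCCGAAAGUCGUCUUUACUACAUGCACGCUACGCCUGAUUCCAUUCGAUCGGCUUCAUCAU
ACACUACGGGCCUUGGCUAACGAAGACCCACUUGGUAAGGCCCAACAGUCAACGUUAUAGCUGUACAGAG
ACAGUACGGAAGAUAUGCGAGUAAGUAUAGCCCGGAUCGGACUGAUUUGGUAUGAGGCAUCACGGAGGGA
UGGGGCGCUAAGGCACUUAUUGGCAAAGCCCAUGUUGCCAGUCCUAGAGAAUUCGGCAAAUACACAAGAC
ACCCCACGUUCGUUAGUGUACAAAGUCGCCACUGAACUGGGUGUUUUCUUCGAUUGUAGAGGCAGGUGGA
AUUUGCAAUAUGAAGGCUGUGUCCUAGCGCAAGUGACCUAGGCAUUAGAAUUUGCGGUAGAGACAGCAAA
GUCAGGUCUCGGCCACAGCCCCGCCCGACCUUAAAGCUCUCAAUACUAUCCGACGAUAAGCCUCGUUAAU
UACACAAGACGUAGGAGUCGGUUGGCUUAAUGAGGCCUCCCUCAAUAACAAAAAAUACUGGGUAGUUUCC
GAGCUUUUAGAGCUAUGCGAGCAGCUCGCGGGCCUAAGUUAUUAGGGACACAUCUUACCUGGGUGCCUCG
GGCGGUUGGGGGUUAGUGUUUAACUAAUAGCAGGCGCCUAGGUUUUCAAGCGGAUUUGUUCAAAGGUAGC
CUCGACCCCCAGCCUUUAUACGUCGAGUGAUCCAAAACGGGGCGGGGUUCCCUCUCUAGAAAUCAUUAGG
CUUUAUCCCCCUGUUACGAGACGCCUCGUACACUAGGCAUUAUCAGAGCAAUGGCCCUAGCCAACGUCUU
CAUGGGUUCAUGCAUAGGUCUCUACCCUGUUCGGACGUUUUGUGGGUCCUCCUGACUCUUACCUCCGGCG
AACAUUUAAGCCCUUCAGGGGCUACUCCCAACUUAUCGGGCCUCUCCCUGCACACUAUGUAACUGAGCUA
CACCCUCCACAAAUAGGGAUAUCAGUUUGCUGAUCGUACCACUAAAAGCGUACUCUUGAAAGUGGGGCGA
GCCUAAGGACGGCCUUGUAGUCAAGGUGGGAAGACCGCGGCCCAAUGACCAACUCUGGAAAAAAUCCCGG
GUCCAUCCCGUUAUUAUACCCCUUACAAAAUCAGGCGAAAAUAAGCCGAUCGUUGCACCUUUUUCGCCAC
GCGUCCUAGCCCGUUACAAAACCGCCUGGCCGUUCCUAGGUACCCGGACCUUGCCUUACAUCGGCGAGAG
CGGAAACCGUUCAAAGUGCCAGGAAAAUGUCUCAAGGGCGAUCUAACACUUAAGGUAGGUAGUACCGUGU
AGACGAGCGCACUAAAGCAAUAGUGUCCCAAUGAAGUGGAGAUUCAAGAUGCAAUCGCCCGCCAAUACUC
GCCUAUCUCCGAGGGAGUUCACUAGGUAAUUCUCACUAAAAAGUGCGACCUGAACACCGAGGCCUACCCC
GUUUCGGCGGUAGUCGCUCCAUUGCGGAACACGGAUCUGGUCCUUGUAUUUCUGGUAGAGGCCAUUAACA
UAGGAAGUGUUCUUACCCUAUCGGCCCUUGGAAUCACACAGCCAUGGUGUGUAAUCCUUUGACCGUAACU
GACUAGAACAAGCUCGGCGUUCCUACCAGUAACAGAGAUAAAAUGCUGAAUUCAGACACCCUCAGAGAAC
GAUACAUGGUCCGUACUCAGCAGCUCCAUAUCUGCCCCACUAAUACACCACUGCGGAACGACUACAUAAG
GGGACACUUUCGGUACCCAGUGCAAGCGUAACUGGCCUCCGAUCAGCAGUUGACGAACCUAAGGAGAUCG
UGUGGUAAGACUCGCAGGAUCGGGUACUGUCUCGAUUAAAGAUGCCGUCGGAAUAGGCGGCGUCCGCUAA
AGACAACACACGCGCCAUUUCGGAAGUCGCUUCUCAGGGCGUAAAGUAUUACUGGCAAGAUCAUAAGGAA
CUCGUUUUACUCCAAGUUUUCGCACUGGCAAUAUGUAUCGAUUCUCUCCUCUUAGGGUAUUCGUAGUCCC
UUACACCGGUAACCGGCUGACGUUUCAGUUCUACUUCGAUGAAACCGCCUGUAAGGGGGGAUGGUAUCAC
CUCUACGUGUCGGGAGGACCUAAGGGUGUUCAGUCCUACUACCGUUUUCCUGUGAUUGACAACGUGUCUU
AAAUCACUACUGUUUUUGGUGAAAGAUCGCUGAUAUAUCUAGUCAAGGACGUCUGUUGUCACCUAAAGGC
CCUCUGCCUCGCGACAAGCCGUGUUCGACUUCGAUAAUACGAUCGUGAUAGCGUUAUAUCUACAGCGGGG
UUAUAAACGAAAUAGCCUCGCAGGUAAGUGCCGGGAGACCCUUCAAGGGCUAUGCAAGGUGGUCGAUCUG
UACAACAAUACGUCGUUCCUCUGGGGAACCUAAAACCUAGUGCUCCGCGGGAGAGUUCUGGCCGGACUCA
CAUGACGGAACAUUUAUGUGGUAGGCGCGACUAUAAUAACAUUAAGCGGGUAUUGAGAUUGACCGGUGUG
CACACGUAGUCUCGUCAUCGUGUCCAUAUGUACGUUUUGAACUCGCAUGCAAGGUCGAGCCCUCGGCGUA
ACACACUGAUCCGACCGAGAACUCCCACAAUUAUAU
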