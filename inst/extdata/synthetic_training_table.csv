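"sequence","lambda_nm","brightness"
"TGGTCTGATG","868.5","0.7523"
"CAAAGGGAGT","676.8","0.6838"
"CATGTTCGAA","646.6","0.7466"
"GAGGGACACG","690.4","1.0822"
"CCGATCATTT","622.6","0.9626"
"TTCCTTAACG","640.1","0.5575"
"TTTATGCGGG","713.1","0.7358"
"GAAAGTGACT","755.3","0.949"
"GTCCACTCGC","517.8","0.9703"
"TTCGTGATGA","775.8","0.4777"
"GAATTATCCG","632","0.5487"
"ATGGCCGCAC","565.9","1.0895"
"GTGGTTTACC","691.6","1.1896"
"CACAAGTGTG","685.6","1.0651"
"GAGGGGGGCT","763.3","0.8033"
"TTCCGCACGT","524.2","1.0842"
"TTCTACCCGA","498.7","0.5305"
"AGCTCGAGTG","693.8","0.4749"
"TGACTATCAG","",""
"TGCTTTCTAT","",""
"CTGATCTTGC","",""
"TCTTACAAAA","",""
"CGTTCTTTAG","",""
"GATATCTCAG","",""
"ACTAAATTAT","",""
"ATATGTGCAT","",""
"CAGATATTAA","",""
"ACCCTGTATA","",""
"AAAATCATCC","",""
"GATGTCCAAC","",""
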