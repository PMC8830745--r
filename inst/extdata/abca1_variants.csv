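residue_id,variant_label,pathogenicity,source
23,C23Y,pathogenic,clinvar
694,L694del,pathogenic,clinvar
774,T774P,pathogenic,clinvar
776,K776N,pathogenic,clinvar
815,E815G,pathogenic,clinvar
825,V825I,pathogenic,clinvar
1329,F1329V,pathogenic,clinvar
1341,R1341T,pathogenic,clinvar
1711,V1711I,pathogenic,clinvar
1731,S1731C,pathogenic,clinvar
1840,F1840fs,pathogenic,clinvar
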