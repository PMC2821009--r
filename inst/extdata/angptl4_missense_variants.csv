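variant,codon_site,distribution_class,assay,polyphen_score,polyphen_prediction,treesaap_category,treesaap_properties
M-1-T,1,Middle,-,NA,benign,none,
P-5-L,5,Middle,-,NA,benign,8,ac:8;an:8;K0:67;Hp:67
E-40-K,40,Significant,-,1.424,benign,8,pHi:8
M-41-I,41,NonSig,-,1.16,benign,none,
S-67-R,67,Middle,-,1.563,possibly damaging,none,
R-72-L,72,Middle,-,1.958,possibly damaging,8,H:8;Hnc:8;an:67
E-167-K,167,Low,LPL Inhib,0.194,benign,8,pHi:8
P-174-S,174,Middle,-,1.715,possibly damaging,none,
E-190-Q,190,NonSig,-,0.243,benign,none,
E-196-K,196,Middle,-,1.541,possibly damaging,8,pHi:8;El:67
G-223-R,223,Low,Secretion,2.065,probably damaging,8,Esm:8
R-230-C,230,Middle,-,2.792,probably damaging,8,pHi:8;Esm:8;Et:8;Br:8;Ns:67;C:67
F-237-V,237,Middle,-,2.51,probably damaging,none,
P-251-T,251,High,Nothing,1.781,possibly damaging,none,
T-266-M,266,NonSig,-,0.783,benign,6-7,K0:67;Ht:67
R-278-Q,278,Significant,-,0.644,benign,6-7,pHi:67
V-291-M,291,Middle,-,1.012,benign,none,
L-293-M,293,Middle,-,1.236,benign,none,
E-296-V,296,Middle,-,2.057,probably damaging,8,Ns:8;Pb:8;Br:67;H:67;Ra:67
P-307-S,307,Middle,-,0.955,benign,6-7,ac:67
V-308-M,308,Middle,-,1.199,benign,none,
R-336-C,336,Low,Secretion,2.255,probably damaging,8,Br:8;pHi:8;Et:8;Ns:67;C:67;Ca:67;Hnc:67
D-338-E,338,Middle,-,1.626,possibly damaging,none,
W-349-C,349,Low,Secretion,3.677,probably damaging,none,
G-361-R,361,Low,Secretion,2.274,probably damaging,8,Ca:8;Esm:8;Mv:67;Mw:67;Hnc:67;V0:67;mu:67
R-371-Q,371,High,Nothing,1.558,possibly damaging,6-7,pHi:67
R-384-W,384,Low,Secretion,2.304,probably damaging,6-7,Br:67;Ht:67
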