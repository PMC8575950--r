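element_id,accession,category,mechanism,organism,freq_lo,freq_hi,titre_tru_per_ml,accessory_orfs,total_orfs,source,printed_frequency,printed_cargo_rate,printed_relmob_lo,printed_relmob_hi,discrepancy
pGO1,NC_012547,plasmid,conjugation,s_aureus,1.4e-7,6.0e-5,,28,55,refs 42;43,6.0 x 10^-5 to 1.4 x 10^-7,0.51 (28/55),7.13e-8,3.05e-5,
pAM387,,plasmid,conjugation,s_aureus,1.1e-6,,,,,ref 44,1.1 x 10^-6,ND,,,
pWBG749e,,plasmid,conjugation,s_aureus,2.8e-5,6.25e-4,,23,52,ref 45,6.25 x 10^-4 to 2.8 x 10^-5,0.44 (23/52),1.24e-5,2.76e-4,
pC223,NC_005243,plasmid,mobilisation,s_aureus,4.5e-6,,,1,5,refs 42;46,4.5 x 10^-6,0.20 (1/5),9.00e-7,9.00e-7,
phiSLT,AB045978.2,phage,lysogenisation,s_aureus,7.69e-3,,,3,60,ref 47,7.69 x 10^-3,0.05 (3/60),3.85e-4,3.85e-4,
80alpha,NC_009526,phage,lysogenisation,s_aureus,1.69e-2,,,3,73,This work,1.69 x 10^-2,0.04 (3/73),6.95e-4,6.95e-4,
phi11,AF424781,phage,lysogenisation,s_aureus,4.62e-1,,,3,53,This work,4.62 x 10^-1,0.06 (3/53),2.62e-2,2.62e-2,
SaPI1,U93688.2,PICI,PICI_transfer,s_aureus,2.46,,,4,26,ref 26,2.46,0.15 (4/26),3.78e-1,3.78e-1,
SaPIbov1,AF217235.1,PICI,PICI_transfer,s_aureus,6.31e-1,,,3,21,ref 26,6.31 x 10^-1,0.14 (3/21),9.01e-2,9.01e-2,
SaPI2,EF010993,PICI,PICI_transfer,s_aureus,2.20e-1,,,2,24,ref 26,2.20 x 10^-1,0.04 (2/24),2.20e-2,2.20e-2,cargo_rate;relmob_lo;relmob_hi
ICE6013,PRJNA360134,conjugative_transposon,conjugation,s_aureus,1.16e-7,,,7,16,ref 48,1.16 x 10^-7,0.44 (7/16),5.08e-8,5.08e-8,
Tn916,U09422,conjugative_transposon,conjugation,s_aureus,6.0e-9,3.4e-8,,2,24,ref 49,6.0 x 10^-9 to 3.4 x 10^-8,0.08 (2/24),5.00e-10,6.25e-11,relmob_hi
CadR_HF1_GT,NC_007795.1,chromosomal_marker,GT,s_aureus,5.58e-6,,,47,47,ref 16,5.58 x 10^-6,1.00 (47/47),5.58e-6,5.58e-6,
CadR_HF3_GT,NC_007795.1,chromosomal_marker,GT,s_aureus,5.69e-6,,,39,39,ref 16,5.69 x 10^-6,1.00 (39/39),5.69e-6,5.69e-6,
CadR_HF5_GT,NC_007795.1,chromosomal_marker,GT,s_aureus,6.31e-6,,,40,40,ref 16,6.31 x 10^-6,1.00 (40/40),6.31e-6,6.31e-6,
CadR_HF7_GT,NC_007795.1,chromosomal_marker,GT,s_aureus,5.12e-6,,,41.5,41.5,ref 16,5.12 x 10^-6,1.00 (41.5/41.5),5.12e-6,5.12e-6,
CadR_HF1_LT,NC_007795.1,chromosomal_marker,LT,s_aureus,5.18e-2,,,17.5,51,ref 16,5.18 x 10^-2,0.34 (17.5/51),1.78e-2,1.78e-2,
CadR_HF3_LT,NC_007795.1,chromosomal_marker,LT,s_aureus,8.00e-3,,,39,39,ref 16,8.00 x 10^-3,1.00 (39/39),8.00e-3,8.00e-3,
CadR_HF5_LT,NC_007795.1,chromosomal_marker,LT,s_aureus,4.51e-3,,,40,40,ref 16,4.51 x 10^-3,1.00 (40/40),4.51e-3,4.51e-3,
CadR_HF7_LT,NC_007795.1,chromosomal_marker,LT,s_aureus,1.45e-3,,,41.5,41.5,ref 16,1.45 x 10^-3,1.00 (41.5/41.5),1.45e-3,1.45e-3,
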