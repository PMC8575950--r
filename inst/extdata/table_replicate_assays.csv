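strain,organism,phage,assay,mean_titre_tru_per_ml,sd_titre,n_replicates,printed_te_per_donor,discrepancy
JP20844,s_aureus,phi11,lysogenisation,3.00e7,2.31e7,4,4.62e-1,
JP20844,s_aureus,phi11,LT_chromosome,5.00e5,1.15e4,4,7.69e-3,
JP20844,s_aureus,phi11,GT_plasmid,2.00e5,1.15e5,4,3.08e-3,
JP20846,s_aureus,80alpha,lysogenisation,1.10e6,6.16e5,4,1.69e-2,
JP20846,s_aureus,80alpha,LT_chromosome,3.25e5,2.63e5,4,5.00e-3,
JP20846,s_aureus,80alpha,GT_plasmid,5.50e4,5.77e3,4,8.46e-4,
JP22210,salmonella,P22,lysogenisation,1.57e8,8.33e7,3,1.567,te_per_donor
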