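treatment,n,pct
any_treatment,12,85.71
behavioral_therapy,7,50
any_pharmacotherapy,11,78.57
centrally_acting_sympathomimetic,5,35.71
SSRI,4,28.57
imidazoline_agonist,3,21.43
anticonvulsant,2,14.29
SNRI,1,7.14
antipsychotic,1,7.14
anxiolytic,1,7.14
atypical_antipsychotic,1,7.14
hypnotic_sedative,1,7.14
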