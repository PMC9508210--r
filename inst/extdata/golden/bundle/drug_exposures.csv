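person_id,start_date,days_supply,treatment_category,source_code
2,2015-09-19,30,SSRI,RXNORM:SSRI
2,2015-10-19,30,SSRI,RXNORM:SSRI
3,2015-08-30,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
3,2015-09-29,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
4,2015-07-01,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
4,2015-07-31,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
5,2015-07-01,30,SSRI,RXNORM:SSRI
5,2015-07-31,30,SSRI,RXNORM:SSRI
5,2015-08-15,30,anxiolytic,RXNORM:anxiolytic
5,2015-09-14,30,anxiolytic,RXNORM:anxiolytic
6,2015-07-01,30,antipsychotic,RXNORM:antipsychotic
6,2015-07-01,90,atypical_antipsychotic,RXNORM:atypical_antipsychotic
7,2015-06-11,30,imidazoline_agonist,RXNORM:imidazoline_agonist
7,2015-07-11,30,imidazoline_agonist,RXNORM:imidazoline_agonist
7,2015-08-10,30,imidazoline_agonist,RXNORM:imidazoline_agonist
8,2015-07-01,30,SNRI,RXNORM:SNRI
8,2015-09-29,30,SSRI,RXNORM:SSRI
8,2015-10-29,30,SSRI,RXNORM:SSRI
8,2016-01-17,30,SNRI,RXNORM:SNRI
9,2016-03-01,90,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
9,2016-03-31,90,imidazoline_agonist,RXNORM:imidazoline_agonist
9,2016-06-09,30,anticonvulsant,RXNORM:anticonvulsant
9,2016-07-09,30,anticonvulsant,RXNORM:anticonvulsant
10,2016-04-20,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
10,2016-05-25,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
10,2016-07-09,30,imidazoline_agonist,RXNORM:imidazoline_agonist
11,2015-07-01,30,hypnotic_sedative,RXNORM:hypnotic_sedative
11,2015-07-21,30,anticonvulsant,RXNORM:anticonvulsant
11,2015-08-31,30,hypnotic_sedative,RXNORM:hypnotic_sedative
12,2015-10-09,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2015-11-08,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2015-12-08,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2016-01-07,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2016-02-06,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2016-03-07,30,centrally_acting_sympathomimetic,RXNORM:centrally_acting_sympathomimetic
12,2016-08-04,30,SSRI,RXNORM:SSRI
12,2016-09-03,30,SSRI,RXNORM:SSRI
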