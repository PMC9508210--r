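person_id,line_number,regimen,line_start,line_end
1,1,behavioral_therapy,2015-07-01,2015-10-09
2,1,behavioral_therapy,2015-07-01,2015-08-14
2,2,SSRI,2015-09-19,2015-11-18
3,1,behavioral_therapy,2015-07-01,2015-08-21
3,2,centrally_acting_sympathomimetic,2015-08-30,2015-10-29
4,1,behavioral_therapy+centrally_acting_sympathomimetic,2015-07-01,2015-11-02
5,1,SSRI,2015-07-01,2015-08-30
5,2,anxiolytic,2015-08-15,2015-10-14
6,1,antipsychotic+atypical_antipsychotic,2015-07-01,2015-09-29
7,1,imidazoline_agonist,2015-06-11,2015-09-09
7,2,behavioral_therapy,2015-10-09,2015-11-29
8,1,SNRI,2015-07-01,2015-07-31
8,2,SSRI,2015-09-29,2015-11-28
9,1,centrally_acting_sympathomimetic+imidazoline_agonist,2016-03-01,2016-06-29
9,2,anticonvulsant,2016-06-09,2016-08-08
10,1,behavioral_therapy,2016-03-01,2016-05-05
10,2,centrally_acting_sympathomimetic,2016-04-20,2016-06-24
10,3,imidazoline_agonist,2016-07-09,2016-08-08
11,1,hypnotic_sedative,2015-07-01,2015-07-31
11,2,anticonvulsant,2015-07-21,2015-08-20
12,1,behavioral_therapy+centrally_acting_sympathomimetic,2015-07-01,2017-06-30
12,2,SSRI,2016-08-04,2016-10-03
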