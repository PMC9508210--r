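person_id,condition_date,condition_category,source_code
1,2015-03-03,developmental_delay,SNOMED:developmental_delay
1,2015-06-01,ADHD,SNOMED:ADHD
1,2015-07-01,ASD,F84.0
1,2015-10-09,ASD,F84.0
2,2015-04-12,developmental_delay,SNOMED:developmental_delay
2,2015-07-01,ASD,F84.0
2,2015-10-09,ASD,F84.0
3,2015-06-16,seizure_disorder,SNOMED:seizure_disorder
3,2015-07-01,ASD,F84.0
3,2015-10-09,ASD,F84.0
4,2015-06-21,ADHD,SNOMED:ADHD
4,2015-07-01,ASD,F84.0
4,2015-10-09,ASD,F84.0
5,2015-07-01,ADHD,SNOMED:ADHD
5,2015-07-01,ASD,F84.0
5,2015-10-09,ASD,F84.0
6,2014-12-13,ADHD,SNOMED:ADHD
6,2015-07-01,ASD,F84.0
6,2015-10-09,ASD,F84.0
7,2015-07-01,ASD,F84.0
7,2015-10-09,ASD,F84.0
8,2015-05-12,anxiety,SNOMED:anxiety
8,2015-07-01,ASD,F84.0
8,2015-10-09,ASD,F84.0
9,2016-01-01,mood_disorder,SNOMED:mood_disorder
9,2016-02-25,anxiety,SNOMED:anxiety
9,2016-03-01,ASD,F84.0
9,2016-06-09,ASD,F84.0
10,2015-09-03,ADHD,SNOMED:ADHD
10,2016-03-01,ASD,F84.0
10,2016-06-09,ASD,F84.0
11,2015-07-01,ASD,F84.0
11,2015-10-09,ASD,F84.0
12,2015-07-01,ASD,F84.0
12,2015-10-09,ASD,F84.0
13,2015-07-01,ASD,F84.0
13,2015-10-09,ASD,F84.0
14,2015-06-21,anxiety,SNOMED:anxiety
14,2015-07-01,ASD,F84.0
15,2015-07-01,ASD,F84.0
15,2016-07-05,ASD,F84.0
16,2015-07-01,ASD,F84.0
16,2015-10-09,ASD,F84.0
17,2015-07-01,ASD,F84.0
17,2015-10-09,ASD,F84.0
18,2014-05-27,ASD,F84.0
18,2015-07-01,ASD,F84.0
18,2015-10-09,ASD,F84.0
19,2017-03-01,ASD,F84.0
19,2017-06-09,ASD,F84.0
20,2015-04-02,anxiety,SNOMED:anxiety
20,2015-07-01,ASD,F84.0
20,2015-10-09,ASD,F84.0
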