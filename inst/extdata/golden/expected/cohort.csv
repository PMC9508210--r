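person_id,index_date,age_at_index,age_group_fine,age_group_coarse,sex,index_year,followup_end
1,2015-07-01,3,0-4,0-9,male,2015,2018-06-30
2,2015-07-01,6,5-9,0-9,male,2015,2018-06-30
3,2015-07-01,8,5-9,0-9,male,2015,2018-06-30
4,2015-07-01,12,10-14,10-17,male,2015,2018-06-30
5,2015-07-01,13,10-14,10-17,male,2015,2018-06-30
6,2015-07-01,16,15-17,10-17,male,2015,2018-06-30
7,2015-07-01,17,15-17,10-17,male,2015,2018-06-30
8,2015-07-01,20,18+,18+,male,2015,2018-06-30
9,2016-03-01,31,18+,18+,female,2016,2019-03-01
10,2016-03-01,8,5-9,0-9,female,2016,2019-03-01
11,2015-07-01,11,10-14,10-17,female,2015,2018-06-30
12,2015-07-01,4,0-4,0-9,male,2015,2018-06-30
13,2015-07-01,9,5-9,0-9,male,2015,2018-06-30
20,2015-07-01,25,18+,18+,female,2015,2018-06-30
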