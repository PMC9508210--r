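person_id,start_date,end_date
1,2015-01-02,2018-10-13
2,2015-01-02,2018-10-13
3,2015-01-02,2018-10-13
4,2015-01-02,2018-10-13
5,2015-01-02,2018-10-13
6,2014-10-24,2018-10-13
7,2015-01-02,2018-10-13
8,2015-01-02,2018-10-13
9,2015-09-03,2019-06-14
10,2015-09-03,2019-06-14
11,2015-01-02,2018-10-13
12,2015-01-02,2018-10-13
13,2015-01-02,2018-10-13
14,2015-01-02,2018-10-13
15,2015-01-02,2018-10-13
16,2015-05-01,2018-10-13
17,2015-01-02,2016-12-31
18,2013-07-31,2018-10-13
19,2016-09-02,2020-06-13
20,2015-01-02,2018-10-13
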