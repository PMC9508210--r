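person_id,birth_year,sex,race
1,2012,male,
2,2009,male,
3,2007,male,
4,2003,male,
5,2002,male,
6,1999,male,
7,1998,male,
8,1995,male,
9,1985,female,
10,2008,female,
11,2004,female,
12,2011,male,
13,2006,male,
14,2005,male,
15,2005,male,
16,2005,male,
17,2005,male,
18,2005,male,
19,2005,male,
20,1990,female,
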