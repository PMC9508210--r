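condition,stratum_type,stratum,n_patients,denominator,pct
ADHD,age_group,0-9,2,6,33.33
ADHD,age_group,10-17,2,5,40
ADHD,age_group,18+,0,3,0
ADHD,overall,overall,4,14,28.57
ADHD,sex,female,1,4,25
ADHD,sex,male,3,10,30
anxiety,age_group,0-9,0,6,0
anxiety,age_group,10-17,0,5,0
anxiety,age_group,18+,3,3,100
anxiety,overall,overall,3,14,21.43
anxiety,sex,female,2,4,50
anxiety,sex,male,1,10,10
mood_disorder,age_group,0-9,0,6,0
mood_disorder,age_group,10-17,0,5,0
mood_disorder,age_group,18+,1,3,33.33
mood_disorder,overall,overall,1,14,7.14
mood_disorder,sex,female,1,4,25
mood_disorder,sex,male,0,10,0
developmental_delay,age_group,0-9,2,6,33.33
developmental_delay,age_group,10-17,0,5,0
developmental_delay,age_group,18+,0,3,0
developmental_delay,overall,overall,2,14,14.29
developmental_delay,sex,female,0,4,0
developmental_delay,sex,male,2,10,20
seizure_disorder,age_group,0-9,1,6,16.67
seizure_disorder,age_group,10-17,0,5,0
seizure_disorder,age_group,18+,0,3,0
seizure_disorder,overall,overall,1,14,7.14
seizure_disorder,sex,female,0,4,0
seizure_disorder,sex,male,1,10,10
malaise_and_fatigue,age_group,0-9,0,6,0
malaise_and_fatigue,age_group,10-17,0,5,0
malaise_and_fatigue,age_group,18+,0,3,0
malaise_and_fatigue,overall,overall,0,14,0
malaise_and_fatigue,sex,female,0,4,0
malaise_and_fatigue,sex,male,0,10,0
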