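table,covariate,level,treated,untreated
all_cohorts,age,<55,77,45
all_cohorts,age,55-65,83,62
all_cohorts,age,65-75,95,136
all_cohorts,age,>75,34,143
all_cohorts,race,White,22,56
all_cohorts,race,Black/African,7,4
all_cohorts,race,Asian,1,2
all_cohorts,race,Unknown,10,36
all_cohorts,sex,Male,162,224
all_cohorts,sex,Female,147,173
all_cohorts,site,Colon,292,365
all_cohorts,site,Rectum,17,32
all_cohorts,grade,I,1,1
all_cohorts,grade,II,15,7
all_cohorts,grade,III,4,3
all_cohorts,histology,AC,36,86
all_cohorts,histology,MC,4,12
all_cohorts,t_stage,T1,4,1
all_cohorts,t_stage,T2,37,95
all_cohorts,t_stage,T3,160,168
all_cohorts,t_stage,T4,35,42
all_cohorts,n_stage,N0,56,161
all_cohorts,n_stage,N1,88,111
all_cohorts,n_stage,N2,73,22
all_cohorts,n_stage,N3,16,9
all_cohorts,tnm_stage,II,86,315
all_cohorts,tnm_stage,III,223,82
test_before_matching,age,<55,14,12
test_before_matching,age,55-65,12,16
test_before_matching,age,65-75,11,38
test_before_matching,age,>75,3,32
test_before_matching,sex,Male,15,63
test_before_matching,sex,Female,25,35
test_before_matching,t_stage,T1,2,1
test_before_matching,t_stage,T2,31,92
test_before_matching,t_stage,T3,7,5
test_before_matching,n_stage,N1,11,80
test_before_matching,n_stage,N2,17,9
test_before_matching,n_stage,N3,12,9
test_before_matching,tnm_stage,II,11,80
test_before_matching,tnm_stage,III,29,18
test_after_matching,age,<55,5,11
test_after_matching,age,55-65,11,7
test_after_matching,age,65-75,10,13
test_after_matching,age,>75,3,13
test_after_matching,sex,Male,14,19
test_after_matching,sex,Female,15,25
test_after_matching,t_stage,T1,1,1
test_after_matching,t_stage,T2,22,39
test_after_matching,t_stage,T3,6,4
test_after_matching,n_stage,N1,11,26
test_after_matching,n_stage,N2,10,9
test_after_matching,n_stage,N3,8,9
test_after_matching,tnm_stage,II,11,26
test_after_matching,tnm_stage,III,18,18
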