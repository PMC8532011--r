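code_set,code_system,pattern
asthma_dx,icd9,493.0x
asthma_dx,icd9,493.8x
asthma_dx,icd9,493.1x
asthma_dx,icd9,493.9x
asthma_dx,icd10,J45.x
copd_dx,icd9,491.22
copd_dx,icd9,491.21
copd_dx,icd9,491.9
copd_dx,icd9,491.8
copd_dx,icd9,493.2x
copd_dx,icd9,492.8
copd_dx,icd9,496
copd_dx,icd10,J42
copd_dx,icd10,J41.8
copd_dx,icd10,J44.*
copd_dx,icd10,J43.*
resp_failure_dx,icd9,518.82
resp_failure_dx,icd9,518.81
resp_failure_dx,icd9,799.1
resp_failure_dx,icd9,518.84
resp_failure_dx,icd10,J96.0*
resp_failure_dx,icd10,J80
resp_failure_dx,icd10,J96.9*
resp_failure_dx,icd10,J96.2*
resp_failure_dx,icd10,R09.2
copd_exacerbation_dx,icd9,491.22
copd_exacerbation_dx,icd9,491.21
copd_exacerbation_dx,icd9,493.22
copd_exacerbation_dx,icd9,493.21
copd_exacerbation_dx,icd10,J44.1
copd_exacerbation_dx,icd10,J44.0
diabetes_dx,icd9,250.x
diabetes_dx,icd9,357.2
diabetes_dx,icd9,362.0x
diabetes_dx,icd9,366.41
diabetes_dx,icd10,E10.x
diabetes_dx,icd10,E11.x
t1d_dx,icd9,250.x3
t1d_dx,icd9,250.x1
t1d_dx,icd10,E10.x
t2d_dx,icd9,250.x2
t2d_dx,icd9,250.x0
t2d_dx,icd10,E11.x
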