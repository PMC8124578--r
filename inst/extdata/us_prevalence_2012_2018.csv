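survey,gender,age_group,year,prevalence,ci_lower,ci_upper
no_nvp_model,male,18+,2012,0.173,,
no_nvp_model,male,18+,2018,0.152,,
tus_cps,male,18+,2012,0.166,,
tus_cps,male,18+,2018,0.129,0.126,0.133
nhis,male,18+,2012,0.205,,
nhis,male,18+,2018,0.158,0.150,0.166
no_nvp_model,male,18-24,2012,0.199,,
no_nvp_model,male,18-24,2018,0.188,,
tus_cps,male,18-24,2012,0.169,,
tus_cps,male,18-24,2018,0.087,0.077,0.099
nhis,male,18-24,2012,0.201,,
nhis,male,18-24,2018,0.085,0.064,0.105
no_nvp_model,male,25-44,2012,0.196,,
no_nvp_model,male,25-44,2018,0.182,,
tus_cps,male,25-44,2012,0.191,,
tus_cps,male,25-44,2018,0.145,0.139,0.151
nhis,male,25-44,2012,0.254,,
nhis,male,25-44,2018,0.191,0.175,0.207
no_nvp_model,male,45-64,2012,0.182,,
no_nvp_model,male,45-64,2018,0.150,,
tus_cps,male,45-64,2012,0.182,,
tus_cps,male,45-64,2018,0.155,0.149,0.161
nhis,male,45-64,2012,0.202,,
nhis,male,45-64,2018,0.183,0.169,0.197
no_nvp_model,male,65+,2012,0.084,,
no_nvp_model,male,65+,2018,0.074,,
tus_cps,male,65+,2012,0.086,,
tus_cps,male,65+,2018,0.084,0.079,0.089
nhis,male,65+,2012,0.106,,
nhis,male,65+,2018,0.099,0.087,0.111
no_nvp_model,female,18+,2012,0.135,,
no_nvp_model,female,18+,2018,0.118,,
tus_cps,female,18+,2012,0.131,,
tus_cps,female,18+,2018,0.100,0.097,0.102
nhis,female,18+,2012,0.158,,
nhis,female,18+,2018,0.120,0.113,0.126
no_nvp_model,female,18-24,2012,0.157,,
no_nvp_model,female,18-24,2018,0.149,,
tus_cps,female,18-24,2012,0.125,,
tus_cps,female,18-24,2018,0.061,0.053,0.070
nhis,female,18-24,2012,0.145,,
nhis,female,18-24,2018,0.073,0.052,0.094
no_nvp_model,female,25-44,2012,0.157,,
no_nvp_model,female,25-44,2018,0.142,,
tus_cps,female,25-44,2012,0.149,,
tus_cps,female,25-44,2018,0.106,0.102,0.111
nhis,female,25-44,2012,0.178,,
nhis,female,25-44,2018,0.142,0.129,0.155
no_nvp_model,female,45-64,2012,0.144,,
no_nvp_model,female,45-64,2018,0.119,,
tus_cps,female,45-64,2012,0.154,,
tus_cps,female,45-64,2018,0.132,0.127,0.137
nhis,female,45-64,2012,0.189,,
nhis,female,45-64,2018,0.143,0.131,0.155
no_nvp_model,female,65+,2012,0.071,,
no_nvp_model,female,65+,2018,0.066,,
tus_cps,female,65+,2012,0.068,,
tus_cps,female,65+,2018,0.063,0.060,0.067
nhis,female,65+,2012,0.075,,
nhis,female,65+,2018,0.073,0.064,0.082
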