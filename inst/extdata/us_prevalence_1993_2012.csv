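survey,gender,age_group,year,prevalence,ci_lower,ci_upper
no_nvp_model,male,18+,1993,0.267,,
no_nvp_model,male,18+,1998,0.252,,
no_nvp_model,male,18+,2010,0.179,,
no_nvp_model,male,18+,2012,0.173,,
tus_cps,male,18+,1993,0.266,0.263,0.270
tus_cps,male,18+,1998,0.244,0.239,0.250
tus_cps,male,18+,2010,0.172,0.168,0.176
nhis,male,18+,1993,0.277,0.266,0.288
nhis,male,18+,1998,0.264,0.255,0.273
nhis,male,18+,2010,0.215,0.207,0.223
nhis,male,18+,2012,0.205,0.196,0.214
no_nvp_model,male,18-24,1993,0.273,,
no_nvp_model,male,18-24,1998,0.290,,
no_nvp_model,male,18-24,2010,0.198,,
no_nvp_model,male,18-24,2012,0.199,,
tus_cps,male,18-24,1993,0.277,0.267,0.287
tus_cps,male,18-24,1998,0.300,0.279,0.320
tus_cps,male,18-24,2010,0.194,0.180,0.207
nhis,male,18-24,1993,0.288,0.255,0.321
nhis,male,18-24,1998,0.313,0.284,0.342
nhis,male,18-24,2010,0.228,0.199,0.257
nhis,male,18-24,2012,0.201,0.171,0.231
no_nvp_model,male,25-44,1993,0.307,,
no_nvp_model,male,25-44,1998,0.281,,
no_nvp_model,male,25-44,2010,0.202,,
no_nvp_model,male,25-44,2012,0.196,,
tus_cps,male,25-44,1993,0.308,0.303,0.313
tus_cps,male,25-44,1998,0.284,0.275,0.294
tus_cps,male,25-44,2010,0.196,0.190,0.203
nhis,male,25-44,1993,0.311,0.295,0.327
nhis,male,25-44,1998,0.294,0.281,0.307
nhis,male,25-44,2010,0.243,0.228,0.258
nhis,male,25-44,2012,0.254,0.238,0.271
no_nvp_model,male,45-64,1993,0.270,,
no_nvp_model,male,45-64,1998,0.260,,
no_nvp_model,male,45-64,2010,0.191,,
no_nvp_model,male,45-64,2012,0.182,,
tus_cps,male,45-64,1993,0.271,0.265,0.277
tus_cps,male,45-64,1998,0.251,0.241,0.262
tus_cps,male,45-64,2010,0.187,0.181,0.193
nhis,male,45-64,1993,0.292,0.272,0.312
nhis,male,45-64,1998,0.277,0.261,0.293
nhis,male,45-64,2010,0.232,0.216,0.248
nhis,male,45-64,2012,0.202,0.188,0.216
no_nvp_model,male,65+,1993,0.136,,
no_nvp_model,male,65+,1998,0.116,,
no_nvp_model,male,65+,2010,0.085,,
no_nvp_model,male,65+,2012,0.084,,
tus_cps,male,65+,1993,0.134,0.128,0.140
tus_cps,male,65+,1998,0.107,0.097,0.117
tus_cps,male,65+,2010,0.086,0.079,0.092
nhis,male,65+,1993,0.135,0.113,0.157
nhis,male,65+,1998,0.104,0.091,0.117
nhis,male,65+,2010,0.097,0.083,0.111
nhis,male,65+,2012,0.106,0.093,0.120
no_nvp_model,female,18+,1993,0.222,,
no_nvp_model,female,18+,1998,0.203,,
no_nvp_model,female,18+,2010,0.140,,
no_nvp_model,female,18+,2012,0.135,,
tus_cps,female,18+,1993,0.223,0.221,0.226
tus_cps,female,18+,1998,0.200,0.195,0.204
tus_cps,female,18+,2010,0.137,0.134,0.140
nhis,female,18+,1993,0.225,0.216,0.234
nhis,female,18+,1998,0.220,0.212,0.228
nhis,female,18+,2010,0.173,0.165,0.181
nhis,female,18+,2012,0.158,0.151,0.165
no_nvp_model,female,18-24,1993,0.237,,
no_nvp_model,female,18-24,1998,0.239,,
no_nvp_model,female,18-24,2010,0.157,,
no_nvp_model,female,18-24,2012,0.157,,
tus_cps,female,18-24,1993,0.239,0.230,0.247
tus_cps,female,18-24,1998,0.247,0.230,0.265
tus_cps,female,18-24,2010,0.147,0.137,0.158
nhis,female,18-24,1993,0.229,0.202,0.256
nhis,female,18-24,1998,0.245,0.219,0.271
nhis,female,18-24,2010,0.174,0.150,0.198
nhis,female,18-24,2012,0.145,0.123,0.167
no_nvp_model,female,25-44,1993,0.263,,
no_nvp_model,female,25-44,1998,0.234,,
no_nvp_model,female,25-44,2010,0.162,,
no_nvp_model,female,25-44,2012,0.157,,
tus_cps,female,25-44,1993,0.264,0.260,0.268
tus_cps,female,25-44,1998,0.238,0.230,0.246
tus_cps,female,25-44,2010,0.157,0.151,0.162
nhis,female,25-44,1993,0.273,0.260,0.286
nhis,female,25-44,1998,0.256,0.244,0.268
nhis,female,25-44,2010,0.198,0.184,0.212
nhis,female,25-44,2012,0.178,0.166,0.190
no_nvp_model,female,45-64,1993,0.231,,
no_nvp_model,female,45-64,1998,0.215,,
no_nvp_model,female,45-64,2010,0.153,,
no_nvp_model,female,45-64,2012,0.144,,
tus_cps,female,45-64,1993,0.232,0.227,0.237
tus_cps,female,45-64,1998,0.205,0.196,0.213
tus_cps,female,45-64,2010,0.159,0.154,0.164
nhis,female,45-64,1993,0.230,0.213,0.247
nhis,female,45-64,1998,0.225,0.212,0.238
nhis,female,45-64,2010,0.191,0.179,0.203
nhis,female,45-64,2012,0.189,0.176,0.202
no_nvp_model,female,65+,1993,0.113,,
no_nvp_model,female,65+,1998,0.098,,
no_nvp_model,female,65+,2010,0.071,,
no_nvp_model,female,65+,2012,0.071,,
tus_cps,female,65+,1993,0.114,0.110,0.119
tus_cps,female,65+,1998,0.096,0.088,0.103
tus_cps,female,65+,2010,0.068,0.064,0.073
nhis,female,65+,1993,0.105,0.092,0.118
nhis,female,65+,1998,0.112,0.100,0.124
nhis,female,65+,2010,0.093,0.081,0.105
nhis,female,65+,2012,0.075,0.066,0.085
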