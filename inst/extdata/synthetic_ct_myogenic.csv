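"sample_id","condition","gene","ct_value","replicate"
"reference_1","reference","PAX7",28.044,1
"reference_1","reference","MYF5",28.799,1
"reference_1","reference","MYOD1",26.67,1
"reference_1","reference","DES",25.926,1
"reference_1","reference","B2M",18.824,1
"reference_1","reference","RPL13A",21.085,1
"reference_2","reference","PAX7",27.768,2
"reference_2","reference","MYF5",28.993,2
"reference_2","reference","MYOD1",26.811,2
"reference_2","reference","DES",26.19,2
"reference_2","reference","B2M",19.156,2
"reference_2","reference","RPL13A",20.874,2
"reference_3","reference","PAX7",27.926,3
"reference_3","reference","MYF5",28.835,3
"reference_3","reference","MYOD1",27.147,3
"reference_3","reference","DES",26.008,3
"reference_3","reference","B2M",18.902,3
"reference_3","reference","RPL13A",21.046,3
"flat_1","flat","PAX7",28.233,1
"flat_1","flat","MYF5",29.138,1
"flat_1","flat","MYOD1",26.738,1
"flat_1","flat","DES",26.225,1
"flat_1","flat","B2M",18.995,1
"flat_1","flat","RPL13A",21.018,1
"flat_2","flat","PAX7",28.625,2
"flat_2","flat","MYF5",29.12,2
"flat_2","flat","MYOD1",26.857,2
"flat_2","flat","DES",26.517,2
"flat_2","flat","B2M",18.762,2
"flat_2","flat","RPL13A",21.063,2
"flat_3","flat","PAX7",28.382,3
"flat_3","flat","MYF5",29.192,3
"flat_3","flat","MYOD1",26.953,3
"flat_3","flat","DES",26.124,3
"flat_3","flat","B2M",19.006,3
"flat_3","flat","RPL13A",20.919,3
"random_1","random","PAX7",26.759,1
"random_1","random","MYF5",28.365,1
"random_1","random","MYOD1",27.162,1
"random_1","random","DES",26.283,1
"random_1","random","B2M",19.099,1
"random_1","random","RPL13A",21.012,1
"random_2","random","PAX7",26.901,2
"random_2","random","MYF5",28.525,2
"random_2","random","MYOD1",27.253,2
"random_2","random","DES",26.001,2
"random_2","random","B2M",18.944,2
"random_2","random","RPL13A",20.929,2
"random_3","random","PAX7",26.79,3
"random_3","random","MYF5",28.687,3
"random_3","random","MYOD1",26.905,3
"random_3","random","DES",26.075,3
"random_3","random","B2M",19.024,3
"random_3","random","RPL13A",20.899,3
"aligned_1","aligned","PAX7",26.508,1
"aligned_1","aligned","MYF5",28.005,1
"aligned_1","aligned","MYOD1",28.407,1
"aligned_1","aligned","DES",25.41,1
"aligned_1","aligned","B2M",18.756,1
"aligned_1","aligned","RPL13A",20.98,1
"aligned_2","aligned","PAX7",26.551,2
"aligned_2","aligned","MYF5",27.989,2
"aligned_2","aligned","MYOD1",28.563,2
"aligned_2","aligned","DES",25.121,2
"aligned_2","aligned","B2M",19.276,2
"aligned_2","aligned","RPL13A",21.052,2
"aligned_3","aligned","PAX7",26.523,3
"aligned_3","aligned","MYF5",27.775,3
"aligned_3","aligned","MYOD1",28.414,3
"aligned_3","aligned","DES",25.181,3
"aligned_3","aligned","B2M",19.003,3
"aligned_3","aligned","RPL13A",20.96,3
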