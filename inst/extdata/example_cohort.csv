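subject_id,diagnosis,visit_month,age,sex,education,icv,lh_bankssts,lh_caudalanteriorcingulate,lh_caudalmiddlefrontal,lh_cuneus,lh_entorhinal,lh_frontalpole,lh_fusiform,lh_inferiorparietal,lh_inferiortemporal,lh_insula,lh_isthmuscingulate,lh_lateraloccipital,lh_lateralorbitofrontal,lh_lingual,lh_medialorbitofrontal,lh_middletemporal,lh_paracentral,lh_parahippocampal,lh_parsopercularis,lh_parsorbitalis,lh_parstriangularis,lh_pericalcarine,lh_postcentral,lh_posteriorcingulate,lh_precentral,lh_precuneus,lh_rostralanteriorcingulate,lh_rostralmiddlefrontal,lh_superiorfrontal,lh_superiorparietal,lh_superiortemporal,lh_supramarginal,lh_temporalpole,lh_transversetemporal,rh_bankssts,rh_caudalanteriorcingulate,rh_caudalmiddlefrontal,rh_cuneus,rh_entorhinal,rh_frontalpole,rh_fusiform,rh_inferiorparietal,rh_inferiortemporal,rh_insula,rh_isthmuscingulate,rh_lateraloccipital,rh_lateralorbitofrontal,rh_lingual,rh_medialorbitofrontal,rh_middletemporal,rh_paracentral,rh_parahippocampal,rh_parsopercularis,rh_parsorbitalis,rh_parstriangularis,rh_pericalcarine,rh_postcentral,rh_posteriorcingulate,rh_precentral,rh_precuneus,rh_rostralanteriorcingulate,rh_rostralmiddlefrontal,rh_superiorfrontal,rh_superiorparietal,rh_superiortemporal,rh_supramarginal,rh_temporalpole,rh_transversetemporal
S0001,CN,0,82.7548,0,19.9283,1408661.0437,2.316,2.5214,2.6349,2.282,2.4068,2.6336,2.7023,2.3493,2.2755,2.5934,2.4206,2.3839,2.3706,2.6784,2.4692,2.2309,2.7339,2.4124,2.2648,2.3551,2.6123,2.4535,2.1472,2.4897,2.5203,2.7568,2.5352,2.3304,2.4249,2.4479,2.2579,2.2942,2.3745,2.1783,2.6333,2.3426,2.4323,2.3124,2.3359,2.1931,2.2949,2.3645,2.2625,2.0558,2.2045,2.6066,2.4454,2.4118,2.4586,2.6108,2.6661,2.5566,2.4368,2.1275,2.2354,2.406,2.5503,2.466,2.4843,2.6008,2.5246,2.5095,2.5342,2.2423,2.3361,2.3041,2.3761,2.3444
S0002,CN,0,73.0765,1,15.2107,1575743.2685,2.3354,2.5541,2.4316,2.4593,2.3615,2.3741,2.4407,2.2915,2.5404,2.7567,2.4786,2.4705,2.6292,2.6704,2.4988,2.3968,2.3342,2.615,2.6049,2.5003,2.3336,2.7353,2.5326,2.4812,2.5472,2.5221,2.5187,2.6287,2.8121,2.689,2.6317,2.4727,2.5177,2.7576,2.5113,2.4988,2.4539,2.4241,2.6739,2.5346,2.6833,2.5564,2.3897,2.5622,2.655,2.4484,2.4327,2.877,3.025,2.4996,2.6178,2.6532,2.3054,2.5077,2.6016,2.5034,2.4416,2.7103,2.4069,2.7496,2.3003,2.7362,2.7748,2.6376,2.7207,2.3342,2.3894,2.6528
S0003,CN,0,77.7156,1,10.9342,1242448.6981,2.534,2.5106,2.6645,2.5562,2.5609,2.34,2.4849,2.4117,2.4048,2.3045,2.6361,2.2833,2.6839,2.4465,2.2686,2.6319,2.2964,2.4747,2.443,2.4104,2.7766,2.314,2.6288,2.6656,2.5213,2.3975,2.4604,2.4066,2.3453,2.4581,2.5104,2.6472,2.4326,2.3655,2.4363,2.6336,2.3193,2.3607,2.477,2.6026,2.3813,2.4212,2.4638,2.4104,2.4325,2.5705,2.4394,2.7753,2.6071,2.4934,2.6764,2.5142,2.1679,2.6259,2.2501,2.4931,2.7037,2.5949,2.5637,2.3698,2.2659,2.244,2.5089,2.3316,2.3978,2.3929,2.3738,2.396
S0004,CN,0,79.0643,1,15.6014,1382331.1487,2.3502,2.5738,2.5223,2.5871,2.4393,2.3022,2.4086,2.395,2.3799,2.4543,2.3998,2.4708,2.323,2.2546,2.577,2.5325,2.366,2.4521,2.5493,2.6742,2.6244,2.3612,2.5939,2.5425,2.8409,2.447,2.5443,2.3542,2.6437,2.2639,2.6455,2.4284,2.7557,2.4305,2.4262,2.5382,2.4716,2.1436,2.3884,2.1612,2.5201,2.7147,2.6683,2.3982,2.5124,2.6067,2.3175,2.2139,2.2909,2.4622,2.5864,2.6958,2.5531,2.7535,2.6292,2.4069,2.2285,2.3737,2.407,2.3553,2.0192,2.3809,2.6334,2.2841,2.3857,2.3518,2.2904,2.6779
S0005,CN,0,77.9213,0,19.6226,1372363.8609,2.6875,2.4844,2.6267,2.5405,2.4435,2.252,2.4525,2.8762,2.1672,2.6511,2.4059,2.3508,2.5391,2.5673,2.554,2.5589,2.3128,2.6924,2.4357,2.4675,2.4669,2.4779,2.4423,2.2845,2.3481,2.6003,2.6198,2.4954,2.4756,2.2749,2.2185,2.5952,2.263,2.3045,2.5606,2.507,2.5692,2.5029,2.5366,2.4334,2.426,2.578,2.5834,2.4283,2.2371,2.2925,2.3258,2.4174,2.3803,2.3651,2.3772,2.2421,2.4599,2.4713,2.2689,2.7015,2.6005,2.614,2.5387,2.5479,2.5956,2.4271,2.5025,2.5601,2.4662,2.142,2.3034,2.4142
S0006,CN,0,75.3694,1,21.5961,1137868.8525,2.4439,2.0597,2.6467,2.3758,2.6486,2.5206,2.5369,2.3043,2.3249,2.4382,2.6132,2.4286,2.5214,2.5811,2.3832,2.7809,2.4118,2.4761,2.4099,2.5453,2.6142,2.356,2.1036,2.7159,2.1917,2.5232,2.3217,2.3231,2.3834,2.3934,2.5217,2.4649,2.4464,2.5287,2.7182,2.4703,2.7302,2.4138,2.5315,2.3314,2.4669,2.9535,2.1879,2.5559,2.4283,2.5268,2.3255,2.7386,2.5642,2.713,2.5209,2.6452,2.423,2.4965,2.4796,2.1831,2.4319,2.5616,2.5638,2.3716,2.5463,2.3152,2.2819,2.3237,2.4549,2.465,2.6031,2.4162
S0007,AD,0,85.056,0,12.716,1505418.391,2.4907,2.4351,2.5005,2.2274,2.5156,2.4904,2.4103,2.413,2.3743,2.3845,2.2339,2.5855,2.5267,2.3914,2.1532,2.4117,2.3646,2.1998,2.5799,2.251,2.2467,2.3349,2.4015,2.5731,2.4334,2.1485,2.3874,2.5493,2.3821,2.3133,2.5954,2.1559,2.4447,2.6602,2.4955,2.532,2.106,2.6205,2.3677,2.6087,2.4743,2.2731,2.2423,2.4518,2.4768,2.3907,2.5178,2.3866,2.1072,2.2279,2.5988,2.1555,2.3457,2.5368,2.392,2.5464,2.1048,2.4234,2.3518,2.325,2.4617,2.4965,2.3957,2.429,2.3389,2.4175,2.3515,2.2172
S0008,AD,0,92.3212,1,16.1119,1530899.79,2.2461,2.2927,2.1913,2.5747,2.5566,2.5279,2.194,1.9738,2.2829,2.3349,2.3417,2.3215,2.3133,2.3705,2.3785,1.8977,2.1676,2.4056,2.307,2.2384,2.1834,2.4787,2.4339,2.4714,2.2447,2.3471,2.3372,2.2751,2.4598,2.1946,2.3064,2.0705,2.5921,2.7111,2.3958,2.548,2.2424,2.4672,2.6508,2.5515,2.1522,2.47,2.3464,2.314,2.321,2.5022,2.515,2.5874,2.0771,2.3135,2.1136,2.436,2.2471,2.3558,2.3459,2.3105,2.0679,2.498,2.4176,2.4682,2.4745,2.2579,2.4555,2.3482,2.2161,2.392,2.309,2.3971
S0009,AD,0,65.1224,0,16.885,1445841.4052,2.4795,2.6249,2.5835,2.6358,2.5257,2.7538,2.6133,2.2265,2.3731,2.4639,2.3643,2.4363,2.7226,2.5095,2.5453,2.4971,2.9026,2.5444,2.7393,2.7468,2.6044,2.7425,2.6039,2.3477,2.664,2.5611,2.4832,2.4754,2.3832,2.5477,2.4722,2.2838,2.6104,2.4356,2.5518,2.4667,2.5504,2.379,2.5177,2.6473,2.5594,2.7618,2.2284,2.3083,2.5798,2.7343,2.5351,2.547,2.4288,2.3949,2.6458,2.6105,2.5735,2.5318,2.6199,2.6604,2.6339,2.7092,2.6832,2.3611,2.5908,2.6356,2.5205,2.2478,2.4151,2.506,2.8565,2.8171
S0010,AD,0,73.337,0,17.9088,1613724.4854,2.6117,2.4626,2.4689,2.3886,2.4729,2.2249,2.3026,2.3941,2.3754,2.3087,2.5504,2.3999,2.1136,2.5807,2.4133,2.5511,2.5415,2.2971,2.1951,2.5641,2.1956,2.583,2.549,2.29,2.2535,2.3812,2.2202,2.383,2.2596,2.3102,2.4853,2.3027,2.5612,2.4483,2.4501,2.3837,2.1259,2.3901,2.3048,2.5898,2.401,2.4205,2.4796,2.1595,2.3646,2.375,2.206,2.6161,2.3232,2.4552,2.5019,2.5205,2.2357,2.1148,2.4652,2.6735,2.8589,2.2814,2.3408,2.0862,2.2095,2.3834,2.3493,2.5523,2.4674,2.2252,2.3666,2.322
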