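muscle,pw_range,ath_0.05,ath_0.10,ath_0.15,ath_0.20,ath_0.25,ath_0.30,ath_0.35,ath_0.40,ath_0.45,ath_0.50
ECU,20-200,0.171,0.139,0.120,0.083,0.050,0.030,0.031,0.087,0.159,0.330
ECU,201-500,0.054,0.028,0.025,0.010,0.026,0.052,0.079,0.107,0.160,0.266
ED,20-200,0.085,0.041,0.0272,0.0270,0.062,0.124,0.176,0.253,0.379,0.719
ED,201-500,0.011,0.034,0.061,0.069,0.096,0.145,0.171,0.225,0.288,0.478
ECRB,20-200,0.226,0.146,0.064,0.025,0.119,0.222,0.335,0.486,0.664,0.931
ECRB,201-500,0.108,0.052,0.013,0.046,0.111,0.190,0.254,0.364,0.469,0.589
ECRL,20-200,0.213,0.177,0.147,0.118,0.088,0.062,0.029,0.040,0.099,0.175
ECRL,201-500,0.083,0.059,0.036,0.014,0.008,0.013,0.045,0.084,0.130,0.180
FCU,20-200,0.093,0.038,0.022,0.029,0.076,0.119,0.172,0.236,0.359,0.515
FCU,201-500,0.013,0.018,0.042,0.071,0.101,0.130,0.160,0.194,0.274,0.640
FDSprox,20-200,0.045,0.062,0.186,0.294,0.468,0.748,0.911,1.367,2.173,26.652
FDSprox,201-500,0.020,0.095,0.179,0.241,0.371,0.483,0.634,0.762,0.900,1.071
FDSdist,20-200,0.170,0.096,0.044,0.050,0.144,0.242,0.369,0.517,0.713,0.937
FDSdist,201-500,0.045,0.017,0.054,0.105,0.159,0.226,0.304,0.362,0.479,0.613
FCR,20-200,0.084,0.043,0.013,0.042,0.073,0.117,0.202,0.291,0.409,0.616
FCR,201-500,0.025,0.005,0.033,0.062,0.082,0.105,0.167,0.229,0.294,0.429
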