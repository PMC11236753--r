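setting,simulation,experiment
muscles,"ECU, ED, ECRB, ECRL, FCR, FDS, FCU","ECU, ED, ECRB, ECRL, FCR, FDS, FCU"
amplitude_mA,1-50 step 1,1-x step 1
pulse_width_us,1-500 continuous,20-100 step 20; 150-500 step 50
motor_response,Muscle-specific ROI activation,Significant increase in force
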