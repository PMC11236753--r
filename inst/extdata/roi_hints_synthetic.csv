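# Synthetic ROI placement hints. The per-muscle segmentation ellipses behind the
# published model are not available, so these cross-section positions (azimuth
# around the section, fractional radius inside the muscle layer), semi-axes and
# orientation angles are plausible defaults by muscle size class and
# flexor/extensor compartment. Override with your own CSV of the same columns.
muscle,azimuth_deg,radius_frac,semi_a_mm,semi_b_mm,pitch_deg,yaw_deg,roll_deg
FCR,235,0.60,8,5,0,0,0
FCU,290,0.65,10,7,0,0,0
FDSdist,260,0.45,10,7,0,0,0
FDSprox,260,0.45,10,7,0,0,0
PL,250,0.70,6,4,0,0,0
PT,225,0.55,8,5,0,0,0
FDPdist,285,0.30,10,7,0,0,0
FDPprox,285,0.30,10,7,0,0,0
FPL,215,0.40,7,5,0,0,0
PQ,255,0.35,6,4,0,0,0
ECRB,165,0.60,8,5,0,0,0
ECRL,180,0.65,8,5,0,0,0
ECU,65,0.65,8,5,0,0,0
ED,105,0.60,10,7,0,0,0
EDM,85,0.55,5,4,0,0,0
APL,140,0.45,6,4,0,0,0
EI,75,0.40,5,4,0,0,0
EPB,130,0.45,5,4,0,0,0
EPL,115,0.40,5,4,0,0,0
SUP,150,0.35,8,5,0,0,0
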