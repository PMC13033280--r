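# description: Diode measurements of Ru-106 plaques (measurement + traceability groups)
name,utype,value_rel,depth_mm,group
Half-life of Ru-106,B,0.04,,ru106_measurement
Half-life resolution (days),B,0.05,,ru106_measurement
Electrometer correction,B,0.1,,ru106_measurement
Temperature correction,B,0.1,,ru106_measurement
Long term stability microSilicon,A,0.1,,ru106_measurement
Measurement repeatability,A,0.3,2,ru106_measurement
Measurement repeatability,A,0.8,10,ru106_measurement
Setup reproducibility,A,0.21,,ru106_measurement
"N_D,w (Co-60)",B,0.5,,traceability_co60
"k_Q,Q0 type A (Co-60)",A,0.2,,traceability_co60
"k_Q,Q0 type B (Co-60)",B,0.5,,traceability_co60
Silicon diode intrinsic sensitivity difference (Co-60),B,1.0,,traceability_co60
"N_D,w (6 MeV)",B,1.1,,traceability_6mev
"k_Q,Q0 type A (6 MeV)",A,0.3,,traceability_6mev
"k_Q,Q0 type B (6 MeV)",B,0.5,,traceability_6mev
Silicon diode intrinsic sensitivity difference (6 MeV),B,1.0,,traceability_6mev
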