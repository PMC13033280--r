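# description: Absorbed dose to water from a Ru-106 source measured with alanine
name,utype,value_rel,depth_mm,group
Alanine calibration coefficient in a Co-60 beam,B,1.2,,
Half-life of Ru-106,B,0.2,,
Time of exposure,B,0.1,,
Temperature correction,B,0.2,,
Difference in alanine intrinsic sensitivity,B,0.5,,
MC correction/conversion factor,A,0.5,,
Setup repeatability and alanine variability,A,2.2,2,
Setup repeatability and alanine variability,A,2.1,3,
Setup repeatability and alanine variability,A,2.1,4,
Setup repeatability and alanine variability,A,3.6,5,
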