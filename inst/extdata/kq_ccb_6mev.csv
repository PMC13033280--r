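# plaque_model: CCB
# quality_Q0: 6MeV
# u_typeA_rel: 0.3
# u_typeB_rel: 0.5
# note: valid only for CCB plaques under the microSilicon measurement setup these factors were computed for
depth_mm,k_value
2,1.01
3,1.01
4,1.00
5,0.98
6,0.97
7,0.96
8,0.95
9,0.94
10,0.93
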