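# plaque_model: CCB
# quality_Q0: Co60
# u_typeA_rel: 0.2
# u_typeB_rel: 0.5
# note: valid only for CCB plaques under the microSilicon measurement setup these factors were computed for
depth_mm,k_value
2,1.14
3,1.13
4,1.12
5,1.10
6,1.09
7,1.08
8,1.07
9,1.06
10,1.04
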