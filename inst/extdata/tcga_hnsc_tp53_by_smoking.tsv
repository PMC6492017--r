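hpv_status	smoking_category	mutated	wild_type	not_available
negative	never_smoked	36	5	0
negative	stopped_gt15y	25	11	2
negative	stopped_lt15y	69	11	2
negative	current_smoker	93	14	7
positive	never_smoked	3	21	0
positive	stopped_gt15y	3	9	0
positive	stopped_lt15y	6	17	2
positive	current_smoker	9	13	1
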