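# Synthetic flux estimates for the toy network (constructed, not measured)
# columns: reaction_id, mean, ci_lower, ci_upper (mmol gDW-1 h-1)
reaction_id	mean	ci_lower	ci_upper
E1	0.45	0.30	0.60
E2	1.00	0.95	1.05
E3	0.05	0.00	0.12
E4	0.05	0.00	0.12
R1	0.45	0.30	0.60
R2	0.50	0.40	0.62
R3	0.50	0.40	0.62
R4	0.04	0.00	0.10
R5	0.04	0.00	0.10
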