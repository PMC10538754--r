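# Demand scenario for the toy network: secretion of D fixed (mmol gDW-1 h-1)
reaction_id	lower	upper
E2	1	1
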