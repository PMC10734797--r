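patient_id,date,code_system,code,setting,qualifier
P01,2017-03-10,AID,18.51.02,aid,none
P02,2017-03-15,ATC,N07XX07,prescription,none
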