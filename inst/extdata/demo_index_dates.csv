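patient_id,date
P01,2017-03-01
P02,2017-03-01
P03,2017-03-01
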