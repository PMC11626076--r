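phantom,ap_cm,ml_cm,scan_length_cm
adult,23,29.5,36
paediatric,17,21.25,16
neonate,11,13,10
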