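aldfa_deg,onset_s
103,24.90
104,19.80
105,21.40
106,20.10
107,18.60
108,15.30
109,16.60
110,11.90
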