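# Single lumped three-element Windkessel standing in for the whole systemic
# circulation, used as the reference afterload of the elastance tuning loop.
# Total resistance 0.17 g/(mm^4 s) gives ~92 mmHg mean pressure at a
# cardiac output of 4.4 L/min; Rd*C ~ 1.7 s matches the systemic decay time.
name,Rp,C,Rd
systemic,0.008,11.0,0.162
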