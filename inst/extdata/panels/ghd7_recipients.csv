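variety,snp05,st6_var
PSB Rc82,T,absent
NSIC Rc158,T,absent
NSIC Rc222,T,absent
NSIC Rc238,T,absent
IR04A115,T,absent
IR05N412,T,absent
PR37951,T,absent
PR38012,T,absent
CT5803,T,absent
CT5805,T,absent
Irga427,T,absent
Parao,A,absent
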