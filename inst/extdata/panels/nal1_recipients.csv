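variety,snp01,snp03,indel3_20bp,ex5_extra
PSB Rc82,A,A,del,absent
NSIC Rc158,A,A,del,absent
NSIC Rc222,A,A,del,absent
NSIC Rc238,A,A,del,absent
IR04A115,A,A,del,absent
IR05N412,A,A,del,absent
PR37951,A,A,del,absent
PR38012,A,A,del,absent
CT5803,A,A,del,absent
CT5805,G,G,ins,absent
Irga427,A,A,del,absent
Parao,G,G,ins,absent
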