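variety,indel1_4bp,snp03
PSB Rc82,ins,T
NSIC Rc158,del,T
NSIC Rc222,ins,T
NSIC Rc238,ins,T
IR04A115,ins,T
IR05N412,ins,T
PR37951,ins,T
PR38012,del,T
CT5803,del,T
CT5805,del,T
Irga427,del,T
Parao,ins,C
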