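variety,snp17,indel1_16bp
PSB Rc82,G,del
NSIC Rc158,G,del
NSIC Rc222,A,del
NSIC Rc238,G,del
IR04A115,G,del
IR05N412,A,del
PR37951,G,del
PR38012,G,del
CT5803,G,del
CT5805,A,del
Irga427,A,del
Parao,G,ins
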