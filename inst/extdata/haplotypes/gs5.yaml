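gene: GS5
description: >
  Promoter allele classes of the grain-size gene GS5 (wide/medium/narrow
  grain), defined by the MG-specific 4-bp promoter indel and the WG-specific
  C/T promoter SNP.
sites:
  - id: indel1_4bp
    description: 4-bp indel in the promoter, 320 bp upstream of the ATG (del = MG)
    alleles: [ins, del]
  - id: snp03
    description: C/T SNP in the promoter (03SNP marker site; C = WG, provisional base assignment)
    alleles: [C, T]
classes:
  - name: WG
    pattern: [ins, C]
    description: wide-grain allele
  - name: MG
    pattern: [del, T]
    description: medium-grain allele
  - name: NG
    pattern: [ins, T]
    description: narrow-grain allele
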