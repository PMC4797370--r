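gene: Gn1a
description: >
  Promoter/5'UTR allele classes of the grain-number gene Gn1a (OsCKX2).
  Types 1-3 are defined by the promoter G/A SNP scored by the 17SNP marker
  together with the 16-bp 5'UTR indel; the yield-positive Habataki allele is
  Type 3.
sites:
  - id: snp17
    description: G/A SNP in the promoter (17SNP marker site)
    alleles: [G, A]
  - id: indel1_16bp
    description: 16-bp indel in the 5'UTR (del = Habataki-like deletion)
    alleles: [ins, del]
classes:
  - name: T1
    pattern: [G, ins]
    description: japonica-type allele (Nipponbare-like), 16-bp segment present
  - name: T2
    pattern: [G, del]
    description: common indica allele, deletion without the promoter SNP
  - name: T3
    pattern: [A, del]
    description: yield-positive Habataki allele
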