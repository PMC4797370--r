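gene: Ghd7
description: >
  Coding-sequence allele classes of Ghd7 relevant to the marker set; the
  fully functional Ghd7-1 allele carries T at CDS position 521 (05SNP marker
  site), the weaker Ghd7-2 allele carries A, and Ghd7-6 is distinguished by
  additional coding differences seen in whole-genome data.
sites:
  - id: snp05
    description: A/T SNP at CDS nucleotide 521 (T = Ghd7-1)
    alleles: [A, T]
  - id: st6_var
    description: additional ST6-type coding differences (WGS evidence)
    alleles: [absent, present]
classes:
  - name: Ghd7-1
    pattern: [T, absent]
    description: fully functional yield-positive allele
  - name: Ghd7-2
    pattern: [A, absent]
    description: functional but weaker allele, common in japonica
  - name: Ghd7-6
    pattern: ["*", present]
    provisional: true
    description: ST6 allele
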