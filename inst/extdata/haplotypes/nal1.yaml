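gene: NAL1
description: >
  Allele classes of SPIKE/NAL1. The japonica-type yield-positive allele
  (Type 5) and the common indica allele (Type 1) are separated by the
  third-exon and fifth-exon G/A SNPs and the 20-bp promoter indel scored by
  the three SPIKE markers. Types 6 and 7 were seen only in whole-genome data
  with an additional fifth-exon coding change and are provisional.
sites:
  - id: snp01
    description: G/A SNP on the third exon (G = japonica, provisional base assignment)
    alleles: [G, A]
  - id: snp03
    description: G/A SNP on the fifth exon (G = japonica, provisional base assignment)
    alleles: [G, A]
  - id: indel3_20bp
    description: 20-bp indel in the promoter, 1.9 kb upstream of the ATG (ins = japonica, provisional)
    alleles: [ins, del]
  - id: ex5_extra
    description: additional fifth-exon amino-acid change detected by WGS (ST6-like lines)
    alleles: [absent, present]
classes:
  - name: Type1
    pattern: [A, A, del, absent]
    description: common indica allele (Takanari-like)
  - name: Type5
    pattern: [G, G, ins, absent]
    description: yield-positive japonica allele (Daringan/Nipponbare-like)
  - name: Type6
    pattern: [A, A, del, present]
    provisional: true
    description: new WGS haplotype with extra fifth-exon change on an indica background
  - name: Type7
    pattern: [G, G, ins, present]
    provisional: true
    description: new WGS haplotype with extra fifth-exon change on a japonica background
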