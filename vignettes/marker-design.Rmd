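---
title: "Models and design choices behind asmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind asmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmarker)
```

# The problem

Marker-assisted selection needs PCR markers that sit inside the target gene
and separate the donor ("positive", P) allele from the recipient
("non-target", N) allele on a cheap readout — an agarose gel, PAGE, or a
capillary trace. `asmarker` models the whole chain: which polymorphism to
use, how to build primers around it, what the PCR will produce on each
allele, what a given electrophoresis system can actually resolve, and what
genotype a scorer would call.

This vignette records the models and the deliberate design decisions, so a
user can judge what a passing test suite does and does not demonstrate.

# Variant scanning

`scan_pair()` aligns two allele sequences of one locus. Because the inputs
are near-identical alleles, a global alignment with affine gap penalties
(match +1, mismatch −1, gap open −4, gap extend −1, via
`Biostrings::pairwiseAlignment`) is appropriate; local alignment would be
wrong here, and a negative total score is treated as "no significant
similarity" and raised as an error. Variants are reported on donor
coordinates (0-based internally, 1-based in all printed tables), as pure
indels without anchor bases, and left-normalized (an indel is shifted left
while the preceding reference base equals the last base of the indel
sequence), so re-normalization is a no-op. The scanner assumes homozygous
inputs; heterozygous donor sequence is out of scope.

`mark_donor_specific()` implements the selection rule used when one donor
must serve many recipient backgrounds: a variant is flagged only if the
donor-vs-recipient comparison shows it against *every* recipient, keyed by
(position, type, ref, alt) on donor coordinates.

`recommend_strategy()` encodes the architecture thresholds:

| variant | rule | architecture |
|---|---|---|
| indel < 20 bp | product capped at 120 bp | `small_indel` |
| indel 20–99 bp | no cap needed | `small_indel` (plain flanking) |
| indel ≥ 100 bp | heterozygote imbalance risk | `large_indel_tri_primer` |
| SNP | single-tube preferred | `snp_tetra_primer`, fallback `snp_separated_AS` |

The tetra-primer assay is preferred for SNPs because it needs one reaction;
the separated allele-specific method is exposed as the fallback because
tetra-primer designs are occasionally unstable in practice.

# Primer engineering

Allele-specific (ARMS) primers end on the allele base. Specificity from the
terminal base alone is weak, so `insert_artificial_mismatch()` adds one
deliberate mismatch near the 3' end. Two choices were open:

* **Offset.** The engineered base is placed at offset 2 from the 3' end by
  default (offset = 1 is the allele base itself). Validation accepts
  offsets 2–4: published marker sets include primers with the substitution
  at offset 4, and the blocking model tolerates any position inside its
  4-nt window.
* **Substituted base.** The substitution is the *complement* of the
  original base. Against the template strand the primer anneals to, this
  yields a purine–purine or pyrimidine–pyrimidine mispair — the most
  destabilizing class — which maximizes discrimination while still allowing
  extension on the matching allele.

Melting temperatures use the unified nearest-neighbor thermodynamic
parameters with duplex-initiation terms, a monovalent-salt entropy
correction of 0.368·(N−1)·ln[Na+], 50 mM Na+ and 250 nM of each strand.
These conditions are fixed package-wide because all designs target one
annealing program; `compute_tm()` is deterministic and validated against an
independent implementation to < 0.5 °C. The design engines filter candidates
to 55–62 °C, ranking by |Tm − 58|; Tm is evaluated on the template-matching
candidate, and the small perturbation from the engineered substitution is
accepted by design.

# Design engines

All four engines share one search discipline: enumerate primer windows
(default lengths 18–28 nt) near the required anchor, keep candidates inside
the Tm range ranked by (|Tm − 58|, product size, leftmost position) for
determinism — no randomness is used anywhere in design — and accept the
first candidate set that passes **verification**: in-silico PCR on both
reconstructed allele templates must reproduce exactly the expected product
set, nothing more. Verification catches secondary binding sites that the
placement arithmetic cannot see. If no candidate verifies, a classed
`asm_design_failure` error names the violated constraint.

Architecture-specific geometry:

* *Indel-spanning*: both products differ by exactly the indel length;
  primers may not overlap on the short allele; for indels < 20 bp both
  products must fit under `max_product_small_indel` (120 bp).
* *Tetra-primer*: inner primers end on the SNP on opposite strands; outer
  primers are placed asymmetrically with allele-product targets 170 bp and
  ≥ 170 + 70 bp, constrained to 120–350 bp each, outer product ≤ 600 bp and
  allele gap ≥ `min_allele_size_gap` (25 bp).
* *Separated allele-specific*: one common primer, two AS primers sharing a
  footprint; product target 220 bp within 120–350 bp.
* *Tri-primer*: flanking pair as close to the indel as Tm allows, plus an
  inner primer inside the insertion placed so the |short-allele − inner|
  gap lands in [25, 150] bp, preferring a 100-bp gap with the inner product
  shorter (matching the published precedent).

# In-silico PCR

The annealing model is intentionally minimal: a primer may prime where its
3'-terminal base pairs, at most `max_mm_window = 1` mismatch falls in the
last `window = 4` nt, and at most `max_mm_total = 3` overall. These defaults
are the loosest rules under which every packaged allele-specific primer
amplifies its matching allele (one engineered mismatch in the window) and is
blocked on the other (terminal mismatch), which is exactly what the
published gel images require. Loosening any allowance only adds sites
(tested as a monotonicity property).

Product lengths count both primer footprints inclusively — the convention
under which the packaged markers' printed sizes are internally consistent
(for the tetra-primer GS5 assay, 257 + 291 − 49 = 499).

Relative efficiency within a reaction is `exp(−λ·(L − L_min))` with
λ = 0.002/bp. This is a one-parameter monotone heuristic, not
thermodynamics: it encodes only "longer products amplify worse in the same
tube". λ was fixed once so that a 625-bp size gap produces a > 3-fold
intensity ratio (the observed near-invisible long band) while a 96-bp gap
stays under 1.3-fold. `simulate_heterozygote()` recomputes efficiencies over
the pooled products of both alleles and flags imbalance when the *strongest
diagnostic band of one allele* is more than 3× weaker than the other
allele's. The per-allele comparison (rather than a global max/min over all
bands) is deliberate: a homozygote's own residual outer band is harmless,
and the quantity of interest is whether each allele remains detectable.

# Virtual gels and genotype calls

Each system has a minimum resolvable gap and a size range:

| system | min gap (bp) | max product (bp) |
|---|---|---|
| 2.5 % agarose | 25 | 3000 |
| 4 % agarose | 8 | 300 |
| 8 % PAGE | 3 | 1000 |
| capillary | 2 | 6000 |

No published numeric limits exist for these thresholds; they are the
calibrated choice consistent with how the fourteen packaged markers were
actually run (4-bp gaps needed PAGE/capillary; 12-, 16- and 20-bp gaps at
small product sizes ran on 4 % agarose; gaps of ~34 bp and larger ran on
2.5 %). The 2.5 % threshold must therefore exceed 20 bp and not exceed
34 bp; 25 bp was chosen and is overridable — pass a modified model to
`resolve_bands()`. Bands closer than the gap merge (intensity-weighted);
bands with pooled efficiency below `display_floor = 0.05` are invisible;
over-range products are flagged unresolved. `recommend_gel()` returns the
cheapest system on which every pair of allele labels yields distinguishable
band patterns, capillary as fallback.

`call_genotype()` matches observed band lengths per reaction to the
design's expected products at the gel's resolution, classifies each matched
band as positive-diagnostic, non-target-diagnostic or common, and calls
PP/NN/PN; missing expected common bands (failed tetra reaction), absent
bands, or unmatchable bands give `invalid` with a diagnostic note. Calls are
monotone under gel improvement: finer systems only refine `invalid` calls
(e.g. a 4-bp heterozygote unreadable on agarose), never contradict a made
call.

# Synthetic fixtures: what they are and are not

For the fourteen packaged markers only the primer sequences, variant
annotations and (where printed) product sizes are public. `build_paper_fixtures()`
therefore *reconstructs* allele templates: primer footprints are laid out at
the spacing implied by the printed sizes, engineered-mismatch positions are
back-translated to template bases by the strong-mispair rule, and all gaps
are filled with seeded 50 %-GC random sequence, re-sampled until no primer
binds anywhere unintended under the default model. Templates of one marker
differ *only* by the annotated variant. Building is deterministic in its
seed.

Where a size was never printed (Gn1a-17SNP, Gn1a-indel3, the SPL14, Ghd7,
SPIKE and TGW6 markers) spacing was chosen once within gel constraints and
the fixture carries `size_exact = FALSE`; these markers are excluded from
exact-size regression, because inventing unprinted numbers and then
"reproducing" them would be circular. Several allele↔base assignments are
not stated in the sources (which of 117/105 bp is the *SCM2* donor allele;
which GS5-03SNP band belongs to which allele; which SNP base is the
japonica *NAL1* allele); the fixtures record one choice and mark it
provisional in their notes. The NAL1 Types 6–7 haplotype patterns rest on
supplementary evidence and are flagged `provisional` in the YAML table.

What passing fixture tests show: the in-silico engine, the length
conventions and the ARMS model are mutually consistent with every printed
band size and gel assignment. What they cannot show: behavior on real
genomic DNA — secondary-structure failures, paralogous binding sites,
polymerase-specific artifacts — because the synthetic backgrounds are
random and uniquely mappable by construction.

# Test problem sizes

The property suites run at sizes chosen to exercise the code thoroughly
while staying quick on one CPU: the binding-site oracle comparison uses 50
random primers (half with planted near-match noise) against a 3-kb
template; the design→PCR→genotype round trip uses 500 random 1–2-kb loci
spanning all four architectures, requiring 100 % correct PP/NN/PN recovery
for every successful design; scan round-trip identity uses 40 pairs with
variants up to 80 bp; genotype-calling regression simulates 200 samples
across all fixtures. Design attempts on random loci may legitimately fail
(no primer window reaches the Tm range near an AT-rich anchor); failures
are counted, not hidden, and the suite asserts a high success floor.

# Known limitations

* Primer cross-dimers, hairpins and multiplex interactions are not
  modeled; the efficiency weight is a heuristic, not kinetics.
* The gel model resolves by length gap only; it ignores absolute-size
  compression at the top of a gel and sequence-dependent migration.
* Heterozygous *input sequences* (for scanning) are unsupported; the
  heterozygote model applies to PCR products of two known homozygous
  templates.
* The Fluidigm-style assay export emits sequence context and dye
  assignments only; instrument-side design is external.
* Haplotype tables are transcriptions; classes resting on partial evidence
  are marked provisional and novel genotype vectors are never
  force-assigned.
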