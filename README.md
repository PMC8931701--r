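# erfscan

Residue-based classification and regulatory analysis of the plant ERF and
DREB transcription-factor subfamilies.

## The problem

The AP2/ERF superfamily — the largest plant-specific transcription-factor
family — is defined by the ~58-residue AP2 DNA-binding domain (Pfam
PF00847). Among the single-AP2-domain proteins, two subfamilies with
distinct regulatory roles are separated by the residues at AP2-domain
positions 14 and 19:

* **DREB** proteins carry V14 (or the conservative substitution I14),
  archetypally V14/E19, and bind the dehydration-responsive DRE/CRT element
  (core `CCGAC`);
* **ERF** proteins carry A14 (or T/S/G/E14), archetypally A14/D19, and bind
  the ethylene-responsive GCC box (core `GCCGCC`).

The residues at positions 9/13/15 further modulate which element a protein
can bind (P9-A14-A15 proteins bind the GCC box strongly; S9 DREBs bind
DRE/CRT; H9 proteins interact with the GCC box, and so on), and many ERFs
carry EAR repression motifs (`LxLxL`, `DLNxxP`) or the EDLL transactivation
motif. During fleshy-fruit development and ripening, these factors sit
downstream of the auxin (IAA) and ethylene (ET) signalling axes: whether a
gene's promoter carries auxin-response (AuxRE/ARF), DRE/CRT or GCC elements,
combined with its expression trend across developmental phases, supports a
direct-versus-indirect regulatory interpretation.

`erfscan` implements that whole desk-side analysis as a tested, reusable R
package for anyone doing genome-wide TF-family surveys: candidate filtering
after an external `hmmsearch`, calibrated diagnostic-residue extraction,
subfamily classification, binding-capability prediction, protein-motif
typing, double-stranded promoter element scanning with overlap/cluster
reporting, TPM trend classification, ΔΔCt relative expression, and the
hormone regulatory-inference decision table — plus a synthetic-data
generator that plants machine-readable ground truth so every stage can be
validated without downloading a genome.

## Core rules

For a protein with AP2-domain diagnostic residues (r9, r13, r14, r15, r19):

* subfamily: `DREB` iff r14 ∈ {V, I}; `ERF` iff r14 ∈ {A, T, S, G, E};
  otherwise unclassified (never silently assigned).
* binding capability (first matching rule fires): S9·V14 → DRE-preferring;
  {N,Q,K,T,I}9·V14·S15 → DRE-preferring; {N,Q,K,T,I,D}9·V14 → both-capable;
  H9 → GCC-preferring; P9·A14·A15 → both-capable (GCC strong); P9 →
  both-capable; else unknown. The table ships as editable YAML.
* expression trend per phase: log2FC = log2((TPM_last + ε)/(TPM_first + ε)),
  ε = 0.1 TPM; `up` iff log2FC ≥ 1, `down` iff ≤ −1, else `flat`.
* hormone inference: IAA uses the development trend and the ARF-site count,
  ET uses the ripening trend and the DRE/CRT + GCC count; a non-flat trend
  with ≥ 1 relevant element is *direct* induction/repression, without
  elements *indirect*; a flat trend yields no call.

## Worked example

```r
library(erfscan)

specs <- data.frame(
  protein_id = c("dreb1", "erf1", "erf2"),
  pos9  = c("S", "P", "P"), pos13 = c("W", "Y", "W"),
  pos14 = c("V", "A", "A"), pos15 = c("S", "A", "A"),
  pos19 = c("E", "D", "D"),
  motifs = c("", "DLNxxP:C;LxLxL:C", ""), length = 160L)
sim <- simulateProteins(specs, seed = 42)

kr <- extractKeyResidues(sim$proteins, sim$hits)
classifySubfamily(kr)
#>   protein_id subfamily rule_fired pos14 pos19
#> 1      dreb1      DREB     V14E19     V     E
#> 2       erf1       ERF     A14D19     A     D
#> 3       erf2       ERF     A14D19     A     D

predictBinding(kr)
#>   protein_id signature       category            rule_fired
#> 1      dreb1   S-W-V-S DRE_preferring            S9_V14_DRE
#> 2       erf1   P-Y-A-A   both_capable P9_A14_A15_GCC_strong
#> 3       erf2   P-W-A-A   both_capable P9_A14_A15_GCC_strong

classifyRepressors(findProteinMotifs(sim$proteins), names(sim$proteins))
#>   protein_id           status n_LxLxL n_DLNxxP
#> 1      dreb1             none       0        0
#> 2       erf1 composite_strong       1        1
#> 3       erf2             none       0        0
```

`dreb1` is called DREB by its V14/E19 pair and predicted DRE/CRT-preferring
from its S9 signature; `erf1`'s planted DLNxxP motif sits within two
residues of an LxLxL, so the two EAR patterns compose into a strong
repressive motif. Promoter scanning works in negative coordinates (−1 is the
base adjacent to the translation start) on both strands:

```r
h <- scanElements(c(promo = "TACCGACAT"),
                  motifs = list(DRE_CRT = c("ACCGAC", "GCCGAC"),
                                ARF = c("TGTCTC", "TGTCGG")))
h
#>   gene_id element_class strand neg_start neg_end   word
#> 1   promo       DRE_CRT      +        -8      -3 ACCGAC
#> 2   promo           ARF      -        -7      -2 TGTCGG
findElementOverlaps(h, minOverlap = 5)$overlap_bp
#> [1] 5
```

The plus-strand DRE/CRT site and the minus-strand ARF site (visible as the
reverse complement `CCGACA`) share 5 bp — the geometry by which
auxin-response and DRE/CRT sites overlap in real promoters.

A full run over FASTA/domtblout/TSV inputs is one call
(`runPipeline(proteins=..., domtbl=..., promoters=..., tpm=...)`), or from
a shell via `inst/scripts/erf-pipeline.R`.

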