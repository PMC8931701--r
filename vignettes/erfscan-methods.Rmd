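---
title: "Methods: residue-based ERF/DREB analysis and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-based ERF/DREB analysis and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erfscan)
```

# Scope and model

`erfscan` analyses the single-AP2-domain ERF and DREB transcription-factor
subfamilies. The package deliberately starts *after* the profile-HMM
search: an external `hmmsearch` against the AP2 model (PF00847) produces a
`--domtblout` table, and everything downstream — filtering, residue
extraction, classification, binding prediction, motif typing, promoter
scanning, expression trends, regulatory inference — is implemented and
tested here. Re-implementing the forward/Viterbi profile search would
duplicate HMMER for no benefit; parsing its stable tabular output is the
correct interface.

## Candidate filtering

Domain hits above the independent E-value cutoff (default 0.001) are
discarded. Proteins are then partitioned by surviving AP2-domain count:
multi-domain proteins (the AP2-subfamily proper) are set aside, and
single-domain proteins carrying a B3 domain are excluded as RAV-type
factors. The B3 exclusion takes an explicit id list rather than running a
second HMM search — it keeps the external-tool surface to one program, and
B3 id lists are cheap to produce. Databases occasionally disagree about
marginal domain architectures; an explicit exclusion-list argument makes
such curation decisions visible and reproducible instead of burying them
in a second search's settings.

## Position numbering and calibration

The diagnostic positions 9/13/14/15/19 are counted "of the AP2 domain",
which we anchor to profile model columns, not to the alignment start: an
N-terminally truncated alignment (e.g. `hmm_from = 12`) still yields
correct residues for the positions it covers, and positions outside the
aligned span are reported as `-`, never guessed. Because a model version
might number columns with a constant shift, `calibrateOffset()` finds the
offset (exhaustive search over −5..+5) that reproduces the known residues
of a reference protein, and errors if none does. The residue at model
column m is read under a gapless mapping
`protein[ali_from + (m − hmm_from)]`; insertions inside the ~58-residue
AP2 domain are rare in genuine family members, and a hit gappy enough to
break the mapping would typically also fail the E-value cutoff. This is a
known limitation: for severely indel-ridden alignments the extracted
residues can be off, which is why the unclassified outcome exists.

When several domain hits survive for one protein, the lowest-E-value hit
is used, ties broken by the smaller alignment start — a deterministic,
order-independent choice.

## Subfamily rule

Position 14 alone separates the subfamilies: V or I → DREB (isoleucine
differs from valine by one methyl group and its codons are single-mutation
neighbours of valine codons, so I14 is treated as a valine variant);
A, T, S, G or E → ERF. Any other residue is `unclassified` with a warning
— the rule tables are exhaustive for curated tomato data but not for
arbitrary input, and silent misassignment would be worse than an explicit
unknown. Physicochemical annotation (hydrophobicity class, polarity,
chemical structure) is a fixed lookup over the residues occurring at the
diagnostic positions; residues outside the table yield `"not tabulated"`.

## Binding-capability prediction

The evidence connecting residue signatures to DRE/CRT versus GCC-box
binding is a compilation of heterogeneous assays (EMSA, yeast one-hybrid,
proteome chip) across species, not a formal rule set. The default table is
a conservative encoding of its summary regularities, applied in priority
order (first match fires): S9 DREBs → DRE-preferring;
{N,Q,K,T,I}9-V14-S15 → DRE-preferring; other {N,Q,K,T,I,D}9-V14 →
both-capable; H9 → GCC-preferring; P9-A14-A15 → both-capable with strong
GCC binding; other P9 → both-capable; anything else → unknown. Position 13
(Y/F/W in ERFs, W in DREBs) is recorded in the signature but gates no
default rule, since no binding conclusion attaches to it. D9 (seen in two
CBFs) has no direct assay evidence; it maps under the both-capable rule
and should be read as low-confidence. The table ships as YAML
(`inst/extdata/binding_rules.yaml`) precisely so users can tighten it as
new assay evidence appears; every pipeline run records the table it used.

## Protein motifs

`LxLxL`, `DLNxxP` and `EDLL` (ExxxxDxxxLxxxL) are matched as exact-residue
patterns where `x` is any of the 20 standard residues — the standard usage
in the EAR-motif literature; a stricter alphabet (e.g. excluding proline
from `x`) can be imposed by post-filtering the hit table. All occurrences
including overlapping ones are reported; counts derive from distinct spans.
The N/C-terminal call compares the hit midpoint with the sequence
midpoint. A DLNxxP hit within two residues of (or overlapping) an LxLxL
hit is typed `composite_strong` — the two EAR patterns fused into one
strong repressive unit; the two-residue gap is a configurable knob because
the biology motivating it ("connected" motifs) is qualitative.

## Promoter scanning

Element detection is exact string matching of a word dictionary on both
strands — no PWM scoring, because the downstream logic consumes discrete
site counts, and a PWM threshold would only smuggle an arbitrary cutoff
into what is presented as a count. Promoter coordinates are negative,
1-based, inclusive, −1 adjacent to the anchor; promoter position i of an
L-bp promoter maps to i − (L + 1). The anchor defaults to the translation
start (configurable to transcription start): ATG positions are
annotated far more consistently across genome versions than TSSs.

The default dictionary is ARF/AuxRE {TGTCTC, TGTCGG}, DRE/CRT
{ACCGAC, GCCGAC}, GCC {GCCGCC}. TGTCTC is the canonical AuxRE;
TGTCGG is included because its reverse complement shares the 5-bp `CCGAC`
core with the DRE/CRT words — the only geometry under which an ARF site
can overlap a DRE/CRT site by exactly 5 bp, a configuration that recurs in
real promoters of this family. Element definitions differ between
databases (PLACE, PlantCARE) and publications rarely print theirs, so
per-gene counts are dictionary-dependent: the dictionary is a config
object, logged with every run, and cross-study count comparisons are only
meaningful under a stated dictionary. Palindromic words hit both strands
over the same span; counting deduplicates spans so such sites count once.
Cluster detection is greedy left-to-right over same-class sites (maximal
runs of ≥ k sites spanning ≤ window bp), which for interval data equals
the exhaustive answer over contiguous sorted runs.

## Expression trends

The trend statistic is the endpoint log2 fold change between the first and
last stage means of a phase, with a pseudo-TPM ε = 0.1 guarding zero
denominators, thresholded at |log2FC| ≥ 1. An endpoint statistic (rather
than a regression over all stages) matches how phase behaviour is
described in this literature — "increased during development" — and is
robust to non-linear within-phase shapes; a Spearman ρ of stage means
against stage order is reported alongside as a monotonicity diagnostic but
never gates the call. The default phase layout is four development stages
(8–28 days post anthesis) and four ripening stages (28–53 DPA) sharing the
28 DPA boundary. "Expressed" means replicate-mean TPM ≥ 1, the
conventional line; it is a parameter because published expressed-gene
counts are threshold-sensitive.

Relative expression from qRT-PCR uses ΔΔCt with amplification efficiency
fixed at 2 (perfect doubling), configurable per primer pair:
fold = E^−((Ct_t − Ct_ref)_sample − (Ct_t − Ct_ref)_calibrator).

## Regulatory inference

The IAA axis combines the development trend with the ARF-site count; the
ET axis combines the ripening trend with the summed DRE/CRT + GCC count
(both element classes are ERF-mediated ethylene-response elements; no
weighting between them is defensible from count data). The trend has
precedence: a flat trend yields no call regardless of element counts — a
promoter full of ARF sites whose gene does not move during development is
evidence of nothing on the IAA axis. Among moving genes, presence of ≥ 1
relevant element upgrades the call from indirect to direct. This four-way
table is the minimal reading consistent with the published per-gene
narratives; known narrated exceptions are trend-consistent under it and
need no special-casing. The table is deterministic and total over its
finite evidence domain, and the test suite checks it by exhaustive
enumeration against an independently hand-written truth table.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the study inputs at
their native scale: ~200 single-AP2 proteins with diagnostic residues
drawn from the empirically observed residue pools (subfamily label fixed
at draw time, *before* any classifier runs), 5,000-bp promoters with
planted elements, and a TPM matrix over eight fruit stages with three
biological replicates and multiplicative lognormal noise (σ = 0.2) —
replicate scatter of TPM values is right-skewed and
variance-stabilised on the log scale, and σ = 0.2 (≈ 20 % coefficient of
variation) is typical for biological replicates of well-expressed genes.
Planted log2 fold changes are {0, ±2}: twofold-per-phase changes on the
development/ripening scale are the magnitude the trend threshold of 1 is
meant to detect.

Backgrounds are scrubbed so the planted truth is exact: protein
backgrounds are re-drawn until they contain no unplanted motif occurrence;
promoter backgrounds are locally mutated (one base inside each spurious
hit, iterated) until the only dictionary hits are the planted ones. Local
mutation is used for promoters because a random 5-kb sequence contains on
the order of 17 spurious dictionary hits, making whole-background
rejection sampling infeasible, while targeted single-base edits converge
in a handful of iterations. The engineered ARF/DRE overlap is the
7-mer `ACCGACA`: a plus-strand `ACCGAC` whose last five bases are a
minus-strand `TGTCGG` site.

What the generator does *not* emulate: homologous sequence similarity
between family members (backgrounds are i.i.d. uniform), indels within the
AP2 domain (domain hits are gapless by construction), compositional bias
in promoters, and count-level quantification noise beyond lognormal TPM
scatter. Passing the planted-truth tests therefore demonstrates that the
detectors are exact on clean signal, not that they are robust to alignment
gaps or to promoter words degenerate with the background — those require
the calibration and configuration mechanisms described above.

# Numerical and interface choices

* Degenerate inputs: empty motif dictionaries, empty phases, negative
  TPM, duplicate FASTA ids, malformed domtblout rows and missing
  reference-gene Ct values all raise immediate, specific errors.
* Ties: best-hit selection breaks E-value ties by leftmost alignment;
  cluster detection is greedy left-to-right, so overlapping candidate
  windows resolve deterministically.
* The open question of whether the published 16-gene EAR count used
  curation beyond pattern matching is resolved here as: pure pattern
  matching, with all hits reported, so any additional curation can be
  applied downstream on the hit table.
* Reproducibility: every randomised component takes a seed; re-running
  the pipeline with identical inputs and configuration reproduces all
  reports bitwise (tested).

# Problem sizes

The shipped tests and the acceptance script use 200 proteins, 50
promoters (5 kb), a 200-gene × 8-stage × 3-replicate matrix, 100-sequence
oracle-equivalence sweeps, and exhaustive (72-combination) enumeration of
the inference domain — sizes chosen to exercise every code path at the
study's own scale while keeping a full run in well under a minute per
component.

# Known limitations

* Residue extraction assumes a gapless hit mapping (above).
* Exact-word promoter scanning cannot reproduce counts produced under a
  different, unpublished element dictionary; treat cross-paper count
  comparisons as dictionary-conditional.
* The binding rule table encodes compiled qualitative evidence; it
  predicts capability classes, not affinities.
* The regulatory decision table is correlative: "direct" means
  trend-plus-element consistency, not a demonstrated binding event.
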