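# Default cis-element word dictionary (exact-match, both strands scanned).
# Edit or extend freely; every pipeline run logs the dictionary it used.
ARF:
  - TGTCTC
  - TGTCGG
DRE_CRT:
  - ACCGAC
  - GCCGAC
GCC:
  - GCCGCC
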