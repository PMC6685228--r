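# Minimal example panel config. Real vendor panels are user-supplied:
# replace the gene list and captured size per the manufacturer's manifest.
name: toy
genes:
  - TP53
  - KRAS
  - EGFR
size_mb: 0.012
include_synonymous: false
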