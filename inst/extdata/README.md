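# Packaged example data

- `markers.tsv`, `groups.tsv` — a **synthetic, illustrative** collagen
  peptide-marker table and its ambiguity groups, built for demonstration and
  testing. The masses are placeholders in the ZooMS screening range; they
  include the shared 1453.7-class peptide and the 1105.6 / 1706.7
  deamidation-target peptides, but they are *not* a curated reference marker
  list. Real analyses must supply curated tables in the same format.
- `site_counts.csv`, `zooms_counts.csv`, `nisp_examples.csv` — published
  assemblage and screening counts for three Uluzzian sites (Uluzzo C rock
  shelter, Roccia San Sebastiano cave, Riparo del Broion), used by the
  worked examples and the reproduction script to exercise the counting and
  rate conventions.
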