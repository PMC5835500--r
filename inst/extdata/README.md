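# Bundled plain-text fixtures

All files here transcribe small published reference tables used by the
validation functions and the acceptance script; nothing is binary.

- `ecad_motifs.tsv` — the four extracellular E-cadherin N-glycosylation
  sequons (N558 NSTY, N570 NGSP, N622 NTSP, N637 NWTI) as reported in
  the glycosylation literature.
- `egfr_motifs.tsv` — the reported extracellular EGFR N-glycosylation
  sequons. The accompanying prose speaks of 13 canonical sites but the
  printed list has 12 sequons; this table carries the 12 printed
  entries verbatim.
- `prediction_validation_counts.tsv` — matched/total peptide counts of
  the predictor-based validation (predicted vs non-predicted Asn sets,
  general and charge/polarity-encoded alphabet). The accompanying text
  mentions 226 predicted sites where the printed table says 229; the
  printed table values are used.
- `published_rules_encoded_pos.tsv` — the 23 printed
  charge/polarity association patterns for glycosylated residues, with
  their confidence and the support levels at which each was emitted.
- `published_rules_general_pos.tsv` — the 8 published general-alphabet
  (raw residue) association patterns for glycosylated residues.

Published rule tables report the support *levels* (thresholds) where a
pattern was emitted, not the pattern's own support, so the
`support_pct` column is absent and read back as `NA`.
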