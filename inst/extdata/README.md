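# Packaged fixtures

All files are plain tab-separated UTF-8 with a header row.

- `early_milk_proteins.tsv` — the 59 proteins detected exclusively in
  early-lactation (6-21 days in milk) bovine milk, with their reported
  protein identifier, curated protein name, and milk-fraction
  localization (`Skimmed`, `MFGM`, or both, semicolon-separated).
  Transcribed from the published curation; one localization cell was
  reconciled against the accompanying text, which enumerates 44
  skimmed-only, 14 MFGM-only and 1 shared protein.
- `milk_dataset_manifest.tsv` — the 35 source proteomics datasets with
  study metadata. `dim` / `dryoff_day` and `max_g` are operational
  encodings of the published free-text descriptors (e.g. "10 d
  post-partum" -> `dim = 10`; plain low-speed skimming -> `max_g = 3000`;
  casein-pelleting (ultra)centrifugation -> `max_g >= 100000`); where a
  descriptor gives only the stage, a representative day inside that
  stage's window was used. The `fraction_class` / `stage_class` columns
  hold the published class assignments and serve as the expected output
  of the classification rules.
- `neb_candidate_evidence.tsv` — declarative evidence flags for the 59
  candidates (tissue proteome hits, metabolic-pathway flags, literature
  support), transcribed from the published per-protein rationale. Input
  to the biomarker-selection step.
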