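# Packaged configuration and fixtures

All files here are plain-text configuration or synthetic fixtures; none
contains real sequencing data or redistributed reference-material
genotypes.

- `panel.tsv` — the panel gene catalog (PANEL-TSV dialect). The 21
  priority and 10 secondary genes transcribe the panel's published gene
  lists; the candidate rows are region placeholders without allele
  definitions. Coordinates are approximate GRCh37 gene spans and are
  configuration, not biology claims.
- `allele_db.tsv` — a small synthetic teaching subset of star-allele
  definitions (ALLELE-TSV dialect) for a handful of core pharmacogenes.
  It is **not** a release of PharmVar/PharmGKB content; defining
  variants are single representative SNVs at plausible GRCh37
  positions.
- `cyp2d6_model_grch37.tsv` — CYP2D6 exon 1–9 segments, the adjacent
  CYP2D7-derived high-homology block, and the CYP2D7/CYP2D8P paralog
  regions masked by the alignment filter (GRCh37; configuration).
- `getrm/` — the synthetic concordance fixture: 250 allele-level
  comparison rows whose category composition transcribes the published
  aggregate breakdown (91.2% concordant before harmonization, 2.8% +
  4.0% nomenclature-driven, 98% after), plus the paired allele database
  and legacy-nomenclature map that make harmonization resolve exactly
  the nomenclature-driven rows. Generated by
  `pgxpanel::write_getrm_fixture()`; the rows are synthetic, not real
  GeT-RM genotypes.
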