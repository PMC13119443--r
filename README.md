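# pgxpanel

Post-sequencing analysis stack for targeted pharmacogenomic (PGx) NGS
panels, for laboratories that already have alignment and primary variant
calling in place and need the PGx-specific layer on top: deterministic
star-allele diplotype calling, CYP2D6 structural-variant detection from
read depth, concordance and analytical-performance reporting for assay
validation, and rare-variant prioritization.

## What it computes

**Star-allele diplotyping.** A star allele is a named haplotype of a
pharmacogene defined by a set of sequence variants (CYP2C19\*2, …);
\*1 is the reference haplotype with an empty defining set. For a gene
with alleles `{a_i}` and defining sets `D_i`, the expected zygosity
profile of an unordered pair (a, b) over `D_a ∪ D_b` is *hom* on
`D_a ∩ D_b` and *het* elsewhere. The engine qualifies VCF calls with
strict thresholds (QUAL > 42 and DP > 30), builds the observed profile
over the gene's definition positions, and enumerates **all** allele
pairs two-by-two, retaining exactly those whose expected profile equals
the observed profile. One match → assigned; several → ambiguous (the
cis/trans ambiguity unphased short reads cannot resolve, reported, never
auto-resolved); none → no call. No probabilistic scoring anywhere.

**CYP2D6 structure.** CYP2D6 sits next to its near-identical paralogs
CYP2D7/CYP2D8P. Alignments with midpoints in paralog regions or low
MAPQ are removed; depth is library-size scaled (panel-wide median),
divided position-wise by a fixed internal control sample, and averaged
per exon. Segment ratios map to copies via bands centered on 0.5 / 1.0 /
1.5 (heterozygous loss / diploid / one extra copy), and the per-segment
pattern classifies whole-gene deletion (\*5), duplication, a
CYP2D6–CYP2D7 hybrid tandem (\*68: focal gain at exon 1 plus the
adjacent homolog block), or deletion co-occurring with a hybrid.

**Validation metrics.** Allele-level concordance against a truth table,
with a nomenclature-harmonization step that re-compares name-discrepant
calls by their defining-variant content (name-version artifacts resolve;
genuine discordance never does); position-wise confusion counts and
accuracy/PPA/NPA/PPV; repeatability and reproducibility as mean pairwise
agreement over replicate call sets; per-gene coverage summaries
(mean depth, % bases ≥ 30×).

**Rare-variant prioritization.** Retains calls that are rare (< 1% in
every available population database), well supported (depth ≥ 30,
QUAL > 42), of damaging consequence class (missense / frameshift /
stop-gained / splice), and backed by at least one evidence line (DANN ≥
0.9, damaging FATHMM/MutationTaster, or non-benign ClinVar); truncating
classes carry evidence intrinsically. Every variant gets an audit-trail
verdict.

A seedable generator (`sim_spec()`, `simulate_sample()`,
`simulate_replicates()`, `build_getrm_fixture()`) produces VCF and
coverage fixtures for all of the above, so the whole stack runs and
tests without protected sequencing data.

## Worked example

```r
library(pgxpanel)

db    <- load_allele_db(allele_db_path())
panel <- load_panel_config(panel_config_path())

spec  <- sim_spec(seed = 12,
                  diplotypes = list(CYP2C19 = c("*1", "*2"),
                                    SLCO1B1 = c("*5", "*5")),
                  cnv_archetype = "deletion_het")
paths <- simulate_sample(spec, db, dir = tempdir(), sample = "patient1")

qcs <- qualify(read_vcf_calls(paths$vcf), qual_thresholds(), "patient1")
call_diplotype("CYP2C19", qcs, db, panel)
#> <diplotype_call> CYP2C19: *1/*2 [assigned]
call_diplotype("SLCO1B1", qcs, db, panel)
#> <diplotype_call> SLCO1B1: *5/*5 [assigned]

model <- load_gene_model_2d6()
np <- normalize_to_control(read_coverage(paths$coverage),
                           simulate_control_coverage(model), model)
classify_structure(np)
#> <cyp2d6_structure_call> copies=1 events=deletion_het
```

The diplotype lines show the assigned unordered allele pair and the
match status; the structure call says one CYP2D6 copy remains, i.e. a
heterozygous whole-gene deletion, exactly the archetype the simulation
spec requested.

```r
fx   <- build_getrm_fixture()
concordance(fx$comparisons)$concordance_pct
#> [1] 91.2
concordance(harmonize(fx$comparisons, fx$db, fx$legacy_map))$concordance_pct
#> [1] 98
```

Harmonization lifts concordance from 91.2% to 98% by resolving exactly
the nomenclature-driven discrepancies (7 + 10 of 250 allele calls); the
5 genuinely discordant calls stay discordant.

## Command line

A thin front end over the same functions ships at
`inst/cli/pgxpanel.R` with subcommands `call`, `concordance`,
`validate`, `simulate` (exit code 2 on input errors):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pgxpanel.R", package="pgxpanel"))')" \
    call --vcf patient1.vcf --coverage patient1.cov.tsv --out-dir out
```

## Scope

The package starts at the VCF/coverage level: demultiplexing, alignment
and primary variant calling are upstream tools' jobs. HLA allele
inference, phenotype (metabolizer-status) translation and clinical
report text are out of scope. See `vignettes/pgxpanel-methods.Rmd` for
the model details, parameter choices and limitations.
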