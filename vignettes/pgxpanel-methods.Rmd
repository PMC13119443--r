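---
title: "Methods: deterministic PGx diplotyping, CYP2D6 structure and panel validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic PGx diplotyping, CYP2D6 structure and panel validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxpanel)
```

This vignette is the package's own account of its methods: the models
and rules each module implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
design was genuinely open.

## 1. Variant identity

Every variant is identified by a normalized `chrom:pos:ref:alt` key.
Normalization trims shared trailing bases, then shared leading bases
(advancing `pos`), always keeping one base on each allele so indels
retain their single-base anchor. This makes key equality well defined
across VCF writers that pad indels differently. The package does not
carry a reference genome, so full left-alignment of indels inside
repeat tracts is out of reach; suffix-then-prefix trimming yields the
minimal representation for every input the stack itself produces, and
allele-definition tables are normalized through the same function, so
matching is internally consistent. Feeding the package VCFs from a
caller that does not left-align is the one case where two spellings of
the same repeat-tract indel could fail to collide; running such input
through `bcftools norm` first removes the issue.

## 2. Call qualification

A candidate call passes iff site quality exceeds 42 **and** depth
exceeds 30 reads — both strict, so quality exactly 42 or depth exactly
30 fails. The quality gate reads the VCF `QUAL` field (the only
universally present variant-level score; genotype `GQ` is not assumed),
and depth comes from `FORMAT/DP` with `INFO/DP` as fallback. `FILTER`
is parsed and surfaced but does not gate: the two thresholds are the
single qualification rule, and a rejected call is treated downstream as
absent (it shows up in false-negative accounting, not as a veto).
Hemizygous genotypes (single allele index, e.g. X-linked G6PD in males)
map to *hom* so the diploid profile matcher still applies.

Note one deliberate asymmetry: the rare-variant filter's depth gate is
**inclusive** (depth ≥ 30) while qualification is strict (> 30). The
two rules come from different parts of the assay's specification and
are implemented verbatim, side by side.

## 3. Diplotype model

For alleles with defining sets $D_a$, $D_b$, the expected zygosity
profile of the unordered pair $(a,b)$ assigns *hom* to
$D_a \cap D_b$ and *het* to the symmetric difference. The observed
profile is the sample's passing calls restricted to the gene's
definition positions (the union of all defining variants of that
gene). The engine enumerates all $\binom{k+1}{2}$ unordered pairs of
the gene's $k$ alleles including self-pairs and keeps exactly the
pairs whose expected profile equals the observed one — same key set,
same zygosities.

Consequences of the perfect-match rule, all deliberate:

- An unexplained passing variant **at a definition position** vetoes
  every pair: the result is `no_call`, not a forced best guess.
  Partial matching would be a probabilistic heuristic, which this
  design rejects for clinical transparency.
- Passing variants inside the gene but **off** the definition
  positions never veto; they are surfaced separately and flow into the
  rare-variant filter.
- Multiple matching pairs are reported as `ambiguous` with the full
  candidate list, sorted deterministically. This is the unphasable
  cis/trans case (e.g. two het variants explained either as one
  compound allele over reference or as two single-variant alleles in
  trans); no frequency prior breaks the tie because any such prior
  would be population-dependent and silent.
- With an empty observed profile the only matching pair is \*1/\*1
  (no other allele has an empty defining set, enforced at load time),
  so "no variants" and "reference diplotype" coincide by construction.

Determinism is structural: candidates are sorted by name, report JSON
has fixed field order, and no hash-order leaks exist, so identical
inputs give byte-identical reports.

## 4. CYP2D6 structure from depth

The CYP2D6 model (packaged for GRCh37; the coordinates are
configuration, not code) lists exons 1–9 — the gene is on the minus
strand, so exon 1 carries the highest genomic coordinate — plus the
adjacent CYP2D7-derived high-homology block at the gene's 5′ end and
the CYP2D7/CYP2D8P paralog spans.

*Paralog filtering.* Reads whose alignment midpoint falls in a paralog
span, or with mapping quality below 20, are dropped before any depth is
computed. The midpoint rule is intentionally simple: a read is
attributed to the locus where most of it aligns, and boundary effects
average out at exon-level resolution. The default MAPQ floor of 20
(1% error) is the conventional "confidently placed" cut-off; in a
region this homologous, most mis-mapped reads carry near-zero MAPQ, so
the exact floor matters little.

*Normalization.* Each coverage profile (sample and control) is first
scaled by the median depth over **all positions it covers** — a
panel-wide library-size correction. The median is used because it is
robust to the very CNV events being detected, but only if the profile
extends well beyond the CYP2D6 footprint: a whole-gene deletion spans
most of the gene model, so a median taken over the model alone would
absorb the event and erase the signal. Profiles must therefore cover
the full panel (the synthetic generator emits a diploid ballast region
for exactly this reason). After scaling, the per-position ratio
sample/control is averaged within each segment; the control is a fixed
diploid reference sample sequenced in every run, which cancels
probe-efficiency structure shared across samples.

*Classification.* Segment mean ratios map to copies through
left-closed bands `[0.25, 0.75) → 1`, `[0.75, 1.25) → 2`,
`[1.25, 1.75) → 3`, centered on the half-steps a diploid locus takes
when one copy is lost or gained. Pattern rules in priority order: all
exons diploid → no event; all exons lost → heterozygous whole-gene
deletion (1 copy); all exons gained → duplication (3 copies); exon 1
and the upstream homolog block gained with exons 2–9 diploid → hybrid
tandem (\*68-type, 2 intact copies plus the hybrid); exons 2–9 lost
with the upstream block gained → deletion plus hybrid (1 intact copy).
Anything else — including ratios at or above 1.75, i.e. amplifications
beyond one extra copy — reports `unclassified` with the per-segment
states intact rather than guessing: the ±50% step logic is only
calibrated for single-copy changes. Segment means (not per-position
voting) drive the bands, matching the exon-level resolution at which
such profiles are reviewed.

In the deletion-plus-hybrid configuration the generator leaves exon 1
at ratio 1.0: the deleted gene copy removes one exon 1 while the
hybrid contributes an extra one, and the two cancel. The classifier's
rule for this pattern deliberately does not constrain exon 1.

## 5. Concordance and harmonization

Truth and test diplotype tables are compared per (sample, gene) as
unordered allele multisets; each of the two alleles is one unit of
comparison, so $n$ (sample, gene) pairs give $2n$ allele-level calls —
the denominator structure used throughout reporting. Exact name
matches are consumed first; remaining alleles are paired by sub-allele
base name (`*2.001` pairs with `*2`, the typical
definition-version discrepancy) and then positionally. Unmatched pairs
are categorized: `test_only_allele` (the test name is absent from the
reference dataset's nomenclature), `reference_only_allele` (the truth
name is absent from the test database), `discordant` otherwise.

Harmonization re-compares the two name-discrepant categories by
**content**: the test allele's defining set (from the test database)
against the reference allele's set (from a legacy-nomenclature map,
same TSV dialect). Identical sets upgrade the row to concordant;
`discordant` rows are never touched; a name missing from its table
leaves the row unchanged with a warning. Two invariants follow and are
tested: harmonization never lowers concordance and never changes the
number of comparisons.

Reported percentages are rounded half-up to one decimal (matching how
such rates are printed); raw fractions are preserved in the JSON.

## 6. Performance metrics

Confusion counts are position-wise over the targeted footprint: TP =
truth variants reported passing with matching zygosity; FN = truth
variants absent, rejected, or zygosity-mismatched; FP = passing calls
not in truth; TN = targeted bases carrying neither a truth variant nor
a passing call. The position-wise TN definition is what gives
specificity-style metrics their large denominator in panel validation.
Metrics are the standard ones — accuracy $(TP+TN)/N$, PPA $TP/(TP+FN)$,
NPA $TN/(TN+FP)$, PPV $TP/(TP+FP)$ — and a metric whose denominator is
zero is reported `NA`, never 0.

Repeatability and reproducibility share one formula and differ only in
pair grouping: for each unordered pair of replicates, agreement is the
share of the union of passing keys on which both agree in key and
zygosity; the metric is the mean over within-run pairs (repeatability)
or across-run pairs (reproducibility), with run membership carried as
replicate metadata.

## 7. Rare-variant cascade

Four sequential gates, each recorded in a per-variant audit trail with
the first failing step: (i) rarity — the maximum over *available*
population frequencies (gnomAD, 1000G, 5000G, dbSNP) below 1%; a
single common report disqualifies, absence from every database counts
as rare; (ii) quality — depth ≥ 30 and the panel-wide quality gate;
(iii) consequence ∈ {missense, frameshift, stop-gained, splice};
(iv) at least one supportive evidence line: DANN ≥ 0.9, a damaging
FATHMM/MutationTaster label, or a ClinVar assertion outside the benign
set. Frameshift and stop-gained variants satisfy (iv) intrinsically —
truncation is its own evidence. The predictor label vocabularies and
the DANN cut-off are configuration with documented defaults, because
the upstream tools publish no universal thresholds; 0.9 is a
commonly used high-specificity operating point for DANN. Monotonicity
(tightening any gate never grows the retained set) is property-tested.

Annotations ride on VCF INFO keys (`GNOMAD_AF`, `KG_AF`, `G5K_AF`,
`DBSNP_AF`, `CSQ`, `DANN`, `FATHMM`, `MT`, `CLNSIG`); absent keys map
to absent fields, never to defaults, and malformed numerics are
collected as record-level errors while the variant stays in play with
the annotation absent.

## 8. Synthetic data: what it does and does not emulate

The generator is first-class, tested code, and its defaults are the
study conditions the rest of the package is exercised under:

- **VCFs** contain exactly the defining variants of the requested
  diplotypes with expected-profile zygosities, QUAL 99, DP 600 —
  600× being a typical hybridization-capture panel depth. Genotypes
  are written unphased (`/`), because the platform being emulated
  cannot phase distant variants and the caller must not rely on phase.
- **Coverage** realizes one of five CYP2D6 structural archetypes
  (diploid, heterozygous deletion, duplication, hybrid tandem,
  deletion plus hybrid) as exact segment ratios times base depth, with
  multiplicative lognormal noise of chosen CV (default 0; 0.1 in the
  robustness suites — capture depth noise at exon scale is
  conventionally ~5–15%, and lognormal keeps depths positive with a
  clean CV parameterization). A diploid ballast region stands in for
  the rest of the panel so the panel-wide scaling median is anchored.
- **Replicates** re-generate the same sample with per-replicate error
  injections (dropped variants, flipped zygosity, degraded quality)
  and run metadata for the two agreement groupings.
- **The concordance fixture** transcribes a published aggregate
  breakdown of 250 allele-level comparisons — 91.2% concordant, 2.8%
  test-only names, 4.0% reference-only names, 2% genuinely
  discordant — with a paired database and legacy map constructed so
  harmonization resolves exactly the nomenclature-driven mass (the
  shares times 250 are integers, asserted at build). The rows are
  synthetic; they are not real reference-material genotypes.

Everything is deterministic under (seed, spec): identical inputs give
byte-identical files.

What passing tests on this data shows — and what it does not. The
suites demonstrate the *logic*: set-algebra correctness of the matcher
against a brute-force oracle, exact recovery of simulated diplotypes
and structural archetypes, arithmetic of the validation metrics, and
robustness of band classification to 10% depth noise. They do not
demonstrate performance on real sequencing: the generator produces no
alignment artifacts, no allele-dropout or strand bias, no probe-
efficiency structure beyond what the control cancels, no multi-allelic
complexity at definition positions, and its allele database is a small
teaching subset rather than a full nomenclature release. Claims about
real-data accuracy require real reference materials.

## 9. Problem sizes and defaults used in the shipped suites

The packaged test and acceptance runs use: the 31-gene
priority/secondary catalog plus 5 candidate placeholders; a toy
database of 28 alleles over 10 genes; 1,000 random oracle cases for
the diplotyper (toy databases of ≤ 6 alleles over ≤ 5 variants); 100
seeded noisy profiles for archetype recovery; replicate sets of 3–4;
and the 250-row concordance fixture. These sizes exercise every code
path and keep the full suite around half a minute on one CPU.

## 10. Known limitations

- Diplotyping is only defined for genes present in the allele
  database; candidate-category genes ship as region placeholders.
- No phasing: ambiguity is reported, not resolved. Orthogonal or
  long-read confirmation is the intended follow-up for ambiguous or
  no-call results.
- CYP2D6 copy-number resolution stops at one extra copy per segment;
  higher amplifications are reported `unclassified` by design.
- Sub-allele resolution goes only as far as defining-variant content;
  alleles identical in content are indistinguishable.
- The CNV module is specific to the CYP2D6 locus model; other
  structurally complex pharmacogenes would need their own gene models
  and, likely, their own pattern rules.
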