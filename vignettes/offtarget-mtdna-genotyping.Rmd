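---
title: "Off-target mitochondrial DNA genotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target mitochondrial DNA genotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offmito)
```

## Scope and rationale

Hybridization-capture experiments (custom gene panels, exomes) enrich
nuclear target regions, but enrichment is leaky: a substantial share of
reads fall off-target, and a small fraction of those — typically a few
hundredths of a percent — originate from true mitochondrial DNA, whose
copy number per cell is high. That residue suffices to genotype the
*MT-RNR1* aminoglycoside-ototoxicity positions (m.1555, m.1494, m.1095 and
a tail of less-established sites) without any dedicated assay. `offmito`
implements the complete path from reads to genotype calls, together with a
simulator that generates capture experiments with known truth, so every
stage is testable end to end on synthetic data.

## Read extraction model

### Alignment

Reads are placed by exact k-mer seeding (default k = 15, every read
offset queried on both strands) followed by full-length ungapped extension.
Scoring is match +1, mismatch −4, so a read of length 100 with *m*
mismatches scores 100 − 5*m*. The method is substitution-focused by
construction: the downstream classifier operates on substitutions, and
indel calling in homopolymer context (the m.961 region) is flagged rather
than attempted, so gapped alignment buys nothing here. The mitochondrial
contig is treated as circular — its k-mers are indexed across the origin
junction and placements wrap — although *MT-RNR1* (positions 648–1601) is
far from the origin, so ordinary runs never exercise the wrap.

Mapping quality is a proxy: the gap between the best and second-best
placement score (the best score itself when only one placement exists).
Published aligners' MAPQ models are calibrated quantities we deliberately
do not imitate; the proxy is an explicit, reproducible filter input with
default threshold 1 (any strictly best placement passes).

### Two-step NUMT relocation

Step 1 aligns every read against the mitochondrial contig alone. Step 2
realigns the step-1 hits competitively against the combined
nuclear + mitochondrial reference; a read is retained as mitochondrial iff
its best combined placement is mitochondrial with a *strictly* higher
score than any nuclear placement. Score ties go to the nuclear genome.
This tie rule is conservative: it minimises false mitochondrial retention
at a small sensitivity cost, because a true mtDNA read whose span covers
no site distinguishing it from a NUMT copy is indistinguishable from a
NUMT read by any alignment evidence. Such reads are counted and reported
(`ambiguous`) so the trade-off is visible rather than silent.

With error-free reads the decision is analytic: a NUMT-origin read
overlapping at least one diverged site scores strictly higher on the
nuclear copy and relocates; a read overlapping none ties and relocates by
the rule. The expected zero-diagnostic fraction for divergence *d* and
read length *L* is (1 − *d*)^*L* (≈ 0.13 at *d* = 0.02, *L* = 100), which
the test suite uses as the analytic bound on wrongly retained NUMT reads.

### Duplicates

PCR duplicates are removed by fragment-coordinate signature: contig, both
mates' start coordinates, strand orientation and read lengths. One
representative per signature survives (lexicographically first fragment
id, for determinism); the operation is idempotent. Distinct fragments that
collide by coordinate are removed too — the standard, accepted bias of
coordinate-based deduplication, negligible at off-target coverage.

## Pileups and metrics

Pileups count A/C/G/T per 1-based mitochondrial position, after two
explicit filters: minimum base quality (default Q20) and minimum
mapping-quality proxy (default 1). External read-counting tools apply
tool- and version-dependent defaults; here the values are configuration,
echoed into every output header. Overlapping mates are counted
independently (naive readcount behaviour); at coverage approaching the
fragment-length scale this double-counts the overlap and is documented as
a VAF bias source. Depth is by definition the sum of the four base counts,
an invariant the tests enforce.

The per-sample coverage median *includes* zero-depth positions — whether
to include them is a genuine convention choice; including them makes the
median reflect the genotyping power over the whole region rather than the
covered subset. The off-target mitochondrial fraction is
`mito_mapped / off_target`, undefined (NA, not zero) when no off-target
reads exist. The off-target–coverage association is ordinary least squares
with Pearson *r* and a two-sided *p* from *t* = *r*·√((*n*−2)/(1−*r*²)) on
*n*−2 df.

## Variant retention and classification

Retention and classification are two separate gates. Retention: at each
position the most frequent non-reference base with at least 2 supporting
reads is a candidate, and PASSes iff VAF = alt/(ref+alt) ≥ 0.10.
Classification then maps the (ref, alt) counts to a genotype class.

Clinical mode, in rule order:

| condition | class |
|---|---|
| depth < 5 | `undetermined` |
| alt = 0 | `wild_type` |
| alt = 1 and depth > 40 | `wild_type_artifact` |
| VAF ∈ [0.10, 0.90], ref > 5, alt > 5 | `carrier_heteroplasmic` |
| VAF > 0.90, ref ≤ 5 | `carrier_homoplasmic` |
| VAF > 0.90, ref > 5 | `manual_review` |
| anything else | `manual_review` |

The heteroplasmy window is *inclusive* at both edges — VAF exactly 0.10 or
0.90 is heteroplasmic — and regression-tested as such. The
single-alternative-read rule encodes the observation that one discordant
read at high depth is either an artifact or heteroplasmy far below the
reportable window; it fires only at depth strictly above 40 with exactly
one alternative read. A VAF above 0.90 with more than 5 reference reads is
*not* auto-called homoplasmic: that much reference signal at high coverage
deserves review (the classic case is VAF 0.93 at 168×), and a reviewer can
promote such calls into the heteroplasmy evidence list explicitly.
Residual configurations (e.g. VAF below 0.10 with several alternative
reads) resolve to `manual_review` rather than silent wild type — clinical
conservatism where no rule clearly applies.

Research low-coverage mode assumes homoplasmy, reflecting panel-scale
mitochondrial coverage of a few reads: alternative reads with zero
reference reads call `carrier_homoplasmic` flagged `low_coverage` (calls
from as little as one read are possible and flagged); mixtures of
reference and alternative reads route to `manual_review` rather than
risking a heteroplasmy claim the data cannot support; the mode's minimum
depth is 1, so only zero-depth sites are `undetermined`. Where exactly to
put the undetermined/wild-type boundary for 1–4 total reads is a
convention, not an empirical fact; both minimum depths are parameters
(`classify_params()`) logged in outputs.

VAF rounding (half-up, two decimals) happens only at the reporting
boundary; all comparisons use raw fractions. Prevalence arithmetic stays
exact until formatting; percent prints in both two-decimal (tables) and
one-decimal (prose) styles, and undetermined samples stay in the
denominator by default (a switch excludes them).

## The synthetic-data generator

`simulate_sample()` draws read pairs from four provenance classes —
on-target nuclear, off-target nuclear, true mitochondrial, NUMT — with the
profile's expected proportions, applies the genotype, then sequencing
error, then duplicates. What it emulates, and how:

- **Regimes.** Presets encode the sample-type regimes of capture
  experiments: custom panels ~50% off-target with ~0.03% of off-target
  mass mitochondrial, exomes ~15% and ~0.02%, FFPE material elevated on
  both axes (73% off-target, mito share calibrated to ~93× at panel
  scale), saliva roughly double blood's mitochondrial share, frozen tissue
  depressed (5% off-target). Preset read totals are cohort-typical (2M
  pairs for panels, 44M–75M for exomes); examples and tests pass smaller
  `total_read_pairs`, which scales coverage proportionally without
  changing the regime. The NUMT share of off-target mass is not an
  observable reported anywhere we know of; the default (half the
  mitochondrial weight) makes NUMT contamination a first-order effect
  without dominating.
- **Fragments.** Uniform start positions per contig; lengths normal(300,
  50) truncated at the read length; no insert-size model beyond that, no
  GC bias, no coverage waviness.
- **Heteroplasmy.** Each mitochondrial fragment carries the alternative
  allele with probability *h*, independently per fragment and per variant
  — the binomial mixing model that makes VAF recovery exactly testable
  against binomial confidence intervals.
- **Error.** Per-base substitutions at a flat rate (default 0.001,
  Q30-consistent); qualities are constant Q30 strings. No indels, no
  FFPE deamination chemistry, no platform-specific error profiles, no
  quality decay along the read.
- **Duplicates.** Post-hoc exact copies of existing fragments, so
  coordinate deduplication can remove them exactly.
- **Determinism.** One master seed; per-sample seeds are a hash of
  (master, sample id), so cohort output is reproducible under reordering.

Consequently, passing tests demonstrate correctness of the *pipeline
logic* under a clean generative model — provenance accounting, NUMT
discrimination at stated divergences, binomial VAF recovery, rule-exact
classification. They do not demonstrate robustness to real-data phenomena
the generator omits: alignment around indels, strand-biased artifacts,
low-complexity mismapping beyond the modeled NUMTs, contamination, or
heteroplasmy linkage across variants (fragments draw alleles
independently).

## Numerical and design choices

- **Coordinates.** External formats keep native conventions (BED 0-based
  half-open; FASTA/VCF/rCRS positions 1-based); internal alignment
  coordinates are 0-based half-open with conversion at the interface, so
  off-by-one ambiguity lives in exactly one place.
- **The *MT-RNR1* span** defaults to 648–1601 (the standard rCRS
  annotation of the 12S rRNA gene) and is overridable: gene-level coverage
  medians depend on it, and it is a convention of this package, not a
  measured quantity.
- **Synthetic reference.** The real rCRS sequence is not bundled; a
  deterministic synthetic 16,569-base sequence stands in, with the
  knowledge-base reference alleles pinned at their positions and the
  m.961 homopolymer context (four cytosines upstream, five downstream)
  reproduced so homopolymer flagging is exercised realistically. Neighbours
  of other pinned positions are arranged so no ≥4-base run touches them,
  keeping the flag specific. Any rCRS-style FASTA can be supplied instead.
- **Homopolymer flagging** marks positions within one base of a run of ≥4
  identical reference bases — the one-base margin is what catches m.961T,
  a single T pinched between two cytosine runs, which is the motivating
  case.
- **Tie-breaks.** Alignment ties resolve by contig order, then start, then
  strand (determinism); the two-step retention tie goes to nuclear
  (conservatism); the variant-candidate tie at equal counts picks the
  alphabetically first base (determinism; at genotyping depth a tie means
  the site is unresolvable anyway and lands in `manual_review`).
- **Seeds below 2³¹**, derived by a small polynomial hash, keep all
  randomness reproducible from one integer.

## Problem sizes

The bundled validation runs at sizes chosen to make the statistics sharp
while staying desk-scale: the exhaustive-oracle comparison uses 250 reads
over a 3 kb circular mito-like contig plus a 2 kb decoy (the oracle scores
every offset, both strands); the NUMT-retention bound uses 10,000
NUMT-origin reads at divergence 0.02; VAF recovery uses five samples at
heteroplasmy 0, 0.3, 0.5, 0.7 and 1 with ≥50× coverage at m.1555 (error
rate 0 in that experiment, so the binomial confidence interval of *h* is
the exact reference distribution); the off-target convergence check uses
100,000 read pairs. The worked-example cohort arithmetic (1,245 samples)
is exact and instantaneous.

## Known limitations

Indels are out of scope end to end (simulator, aligner, caller); m.961
homopolymer indels are flagged, never called. The aligner is ungapped and
will lose reads spanning true structural differences. VAF near
fragment-scale coverage inherits the overlapping-mate double-count. NUMT
handling is alignment-based only; no VAF-level NUMT correction is
attempted beyond relocation. Haplogroup assignment and full mitochondrial
annotation are non-goals.
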