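---
title: "Methods: somatic cohort analysis on synthetic tumor–normal pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic cohort analysis on synthetic tumor-normal pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somacohort)
```

# Scope and model

`somacohort` implements the post-calling analysis chain for a cohort of
tumor–normal WGS pairs from a low-burden tumor entity with two
histological subtypes (ACP-like and PCP-like) driven by mutually
exclusive events: a mutation cluster region in the exon 3 of a
β-catenin-like gene, and a V600E-like hotspot substitution. The chain is
consensus filtering → coding annotation → mutational spectra → signature
refitting → kataegis/terminal analysis → cohort statistics. Each stage is
an exported function; `run_pipeline()` wires them together over a
synthetic cohort whose truth is known, so accuracy is measurable.

# Consensus and threshold filtering

Per tumor, three call sets are merged on (chrom, pos, ref, alt): caller A
(Mutect2-like, SNVs with PASS flags), caller B (Strelka2-like, SNVs and
InDels) and caller C (Varscan2-like, InDels with a p-value). Evidence
fields are taken from A when present, else B, else C, and the source is
recorded. The final set keeps SNVs only if A called them with PASS, and
InDels only if both B and C called them; records failing this rule are
tagged `CALLER_CONSENSUS`. Whether an SNV confirmed by both secondary
callers but missed by A should survive is genuinely ambiguous; we adopt
the strict primary-PASS reading and expose the rule in `filter_cohort()`
so the alternative is a one-line change.

Threshold rules, each independently evaluated so failures enumerate
rather than short-circuit:

| rule | default | reading |
|---|---|---|
| `VAF` | ≥ 0.10 | caller-reported allele fraction, not recomputed |
| `BQ` | ≥ 20 | site mean base quality (per-alt-read mean is not modelled) |
| `DEPTH_NORMAL` / `DEPTH_TUMOR` | > 14 / > 8 | SNVs; "over" read as strictly greater; 14 maps to the normal following the normal/tumor ordering |
| `INDEL_DEPTH` | > 10 | tumor depth at InDel loci |
| `INDEL_P` | ≤ 0.001 | only when caller C reported the InDel |
| `PON` | — | exact (chrom, pos, alt) membership in the panel of normals |
| `MASK` | — | overlap with the low-complexity BED; InDels use the full REF footprint, so deletions spanning a repeat edge are caught |

The panel of normals admits a site observed in at least
`min_supporting_normals` distinct normals; the default of 1 is the
conservative choice (any normal evidence removes the site). All
thresholds are arguments of `filter_thresholds()`.

# Coding annotation

The region taxonomy is deliberately coarse — exonic (overlaps any CDS),
intronic (inside a transcript span), intergenic — because only CDS
effects feed the downstream tables; UTR-like exon sequence folds into
"intronic". When transcripts disagree, the longest CDS wins, ties broken
by alphabetical gene name, making reports deterministic. For SNVs the
reference codon is rebuilt from CDS coordinates strand-awarely,
substituted and translated with the standard code; stop gains are named
with `X` (`p.W425X`). InDels with a length change divisible by 3 are
in-frame (`p.P44_D56del` for a codon-aligned deletion), all others
frameshifts named at the first affected codon (`p.K7fs`). Stop-loss and
splice classes are not modelled. The translation path is tested against a
full-protein translate-and-diff oracle on hundreds of random CDS
variants, on both strands.

# Spectra and signature refitting

Substitutions collapse onto the pyrimidine strand: six classes and 96
trinucleotide channels in the conventional order (C>A, C>G, C>T, T>A,
T>C, T>G × 16 flank pairs, lexicographic). Variants with an N flank are
excluded and counted. Cohort spectra are pooled counts by default;
per-sample proportion averaging is available (`cohort_spectrum(method =
"mean")`) since published figures rarely say which convention they use.
InDels never enter spectra; they do enter rainfall/kataegis.

Refitting expresses an observed 96-channel frequency vector as a
non-negative weighted sum of reference signature columns. The algorithm
is iterative forward selection: each round evaluates, for every allowed
signature, the best single-weight value in [0, 1] by golden-section
search (interval tolerance 1e-4), accepts the best change if it improves
the squared reconstruction error by more than `tol` (default 1e-3), and
then refines the weights of the signatures selected so far by coordinate
descent to convergence. After the loop, weights below `cutoff` (default
0.06) are zeroed and the search re-runs restricted to the survivors;
weights are constrained to sum to at most 1, with optional
renormalization to exactly 1 (off by default, since an incomplete fit is
information). The split of roles — `tol` decides *which* signatures
enter, refinement decides *how much* — matters: using `tol` to stop
refinement too leaves fits far from the constrained least-squares
optimum, and the test suite holds the fitted SSE to within 1e-4 of an
exhaustive grid search at 0.001 resolution for up to three signatures.
A consequence worth knowing: a genuinely present but flat, low-weight
process (weight ≲ 0.15 for broad shapes) may never clear the entry
threshold — the same insensitivity the widely used per-patient refitting
tools show.

The bundled `synthetic_signature_matrix()` provides five deterministic,
span-limited shapes (a CpG-peaked clock-like process, a broad
C:G>T:A + T:A>C:G process, and three further peaked/flat shapes on the
remaining classes). Shapes were chosen once so that exposures are
identifiable under refitting — each signature owns its substitution
groups — and are a stand-in catalogue, not a copy of any proprietary
one. Real analyses pass their own matrix via `read_signature_matrix()`.
No trinucleotide-abundance renormalization is applied between observed
counts and signature space: whole-genome counts fit genome-normalized
signatures directly.

# Kataegis and terminal enrichment

A kataegis event is the community operational definition: at least
`min_n = 6` consecutive mutations with mean inter-mutation distance at
most `max_mean_imd = 1000` bases. Detection scans every window size per
chromosome (a window of one size can qualify when no smaller window
does, so sizes cannot be pruned), marks members, and reports maximal
runs of consecutive members as events. Two caveats are documented rather
than hidden: a merged run's own mean IMD can exceed the threshold even
though every mutation in it belongs to some qualifying window (the
event's `mean_imd` is reported as-is), and at desk-scale mutation
densities (~1000× the per-base density of a real genome) background
kataegis events are expected, particularly inside terminal windows when
`terminal_bias > 0`. Planted-cluster recall, which is what the truth set
can score, is unaffected.

Terminal windows are the outermost 5% (configurable) of each
chromosome's non-gap span, per end — the quantification is this
package's choice, since "close to the telomeres" has no standard width.
The enrichment test compares the observed fraction of mutations in those
windows against `n_perm` placements drawn uniformly over non-gap bases,
with `p = (1 + #[perm ≥ obs]) / (n_perm + 1)`. The null ignores
trinucleotide composition; that is the simplest defensible choice and a
known limitation. The published observation this formalizes was
descriptive — the test itself is an addition, and reports label it so.

# Cohort statistics

TMB divides mutation counts by callable megabases; the default
denominator 3,088.27 Mb is the non-gap length of a human reference
genome, and synthetic runs pass their own genome size. Percentages round
half-up to 2 decimals, TMB to 3, matching how such values are printed.
The age–burden association uses Pearson's r with the two-sided t
transform on n − 2 degrees of freedom (`stats::cor.test`); both total
mutations and SNV-only counts are supported since published phrasing
rarely distinguishes them. Driver mutual exclusivity builds the
subtype × mutant 2×2 table and computes the two-sided Fisher exact p by
direct hypergeometric enumeration (`stats::dhyper` terms, no continuity
adjustments); `stats::fisher.test` serves as an independent oracle in the
tests, never as the implementation. Samples carrying both drivers are
reported, not suppressed: exclusivity is a finding, not an assumption.
Driver genotypes are defined by the precise loci — any non-silent coding
variant in the exon-3-like codon 30–60 region, and the exact V600E-like
protein change — not by "any hit in the gene", which at WGS scale would
be contaminated by passengers.

# The synthetic cohort generator

Defaults are the study conditions the package is built around: 16
ACP-like and 10 PCP-like pairs; per-tumor expectations of 760 SNVs and
39 InDels; a signature mixture of 0.65 broad + 0.18 clock-like with the
remaining mass assigned to unnamed catalogue processes (each below the
0.06 reporting cutoff — modelling "scarcely contributing" background
rather than a flat channel floor, which least squares would partially
absorb into the broad signature); driver carrier fractions 11/16 and
7/10, mutually exclusive, with one ACP-like carrier receiving the
compound event (codon-43 transversion plus 39-nt in-frame deletion of
codons 44–56) instead of the hotspot substitution; kataegis clusters per
`kataegis_spec`; 30% of SNVs forced into terminal windows; and caller
noise of 2% FN per caller plus ~60 FP records per tumor split across
recurrent artifact sites, masked regions and low-VAF positions.

Scales are desk-sized by design: 2–5 chromosomes of 0.2–2 Mb (default
2.4 Mb over three chromosomes) with telomere-like N gaps at both ends
and one interior gap. All rates are per-genome, so the downstream math
is scale-free; the test suite runs cohorts from 4 to 26 samples and the
acceptance script uses the full 26-pair default (≈ 20,000 variants) —
sizes chosen to keep any single check in seconds to a couple of minutes.

Distributional choices the generator fixes (none of which a published
methods section specifies): per-sample burden is Poisson around an
age-scaled mean, `λ_i = mean_snv · ((1−a) + a·age_i/mean(age))` with
`a = age_effect = 0.5`, times a lognormal overdispersion factor
(σ = 0.3, mean-corrected) — pure Poisson gives an age correlation near
0.99, far tighter than any real cohort, while the overdispersed default
lands near r ≈ 0.5–0.7; base qualities are round(N(32, 4)) clipped to
[2, 40]; true VAFs are U(0.2, 0.5); artifact sites recur in ≥ 2 normals
with VAF U(0.02, 0.08). True-variant evidence is drawn from the passing
region of threshold space (tumor depth ≥ 15, normal ≥ 16, alt reads
floored at 12% VAF, base quality ≥ 22): the planted truth thereby
represents the *detectable* somatic set, the caller FN rate is the only
source of missed truth, and a zero-noise configuration round-trips
exactly — which is what makes filter precision/recall against truth a
meaningful score rather than a property of unmodelled evidence noise.

What the generator does **not** emulate: read-level data (no FASTQ/BAM),
sequencing error profiles, copy number, structural variants,
purity/ploidy, subclonality, and realistic genome composition
(trinucleotide abundances are those of a random sequence). Passing tests
therefore demonstrate the correctness of the analysis logic on data with
the assumed statistical structure, not robustness to artifacts these
unmodelled processes create in real data.

# Numerical and degenerate-input conventions

Seeded determinism everywhere: every stage derives an independent stream
from the master seed, so outputs are byte-identical across runs.
Position collisions while planting resolve in favour of drivers, then
kataegis members, then background. Empty inputs return typed empty
results (empty truth sets, all-zero spectra with NA proportions,
zero-row event tables); refusals are errors with the offending quantity
named (low-count samples below 50 mutations, SNVs carrying an InDel
p-value, contradictory reference alleles at one site, channels with no
matching genomic position). Ties in transcript choice and channel
ordering are broken deterministically as described above.
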