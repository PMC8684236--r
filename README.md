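# somacohort

Cohort-scale analysis of somatic small variants from whole-genome
sequencing of tumor–normal pairs, built for studies of low-burden tumors
such as craniopharyngioma (ACP/PCP), where a handful of recurrent drivers
— β-catenin exon-3 mutations in the adamantinomatous subtype, BRAF V600E
in the papillary subtype — sit on a sparse background of passenger
mutations. The package re-implements, as tested reusable components, the
standard analysis chain such a study runs after variant calling:

* **Consensus filtering** of multi-caller call sets. SNVs are kept when the
  primary caller (Mutect2-like) reported them as PASS; InDels when both
  InDel callers (Strelka2-like and Varscan2-like) agree. Threshold rules are
  applied on top and every failure is enumerated: VAF ≥ 10%, mean base
  quality ≥ 20, read depth > 14/8 in normal/tumor for SNVs, InDel depth
  > 10 and InDel p ≤ 0.001, removal of panel-of-normals background sites
  and of calls in low-complexity (tandem-repeat) regions.
* **Coding annotation** against a gene model: exonic/intronic/intergenic
  region classes, strand-aware codon reconstruction and translation for
  missense/silent/nonsense calls (`p.W425X`-style naming), in-frame vs
  frameshift InDels (`p.P44_D56del`, `p.K7fs`).
* **Mutational spectra**: the six base-pair substitution classes
  (C:G>T:A, …) and the 96 trinucleotide channels `X[R>A]Y` with purine
  sites collapsed onto the pyrimidine strand.
* **Signature refitting**: non-negative exposures of reference signatures
  fitted per sample by iterative forward selection with golden-section
  line search, a 0.06 discard cutoff, and weights constrained to the unit
  simplex — the deconstructSigs-style per-patient contribution analysis.
* **Kataegis and terminal enrichment**: inter-mutation distances
  (rainfall), clustered-mutation events (≥ 6 mutations with mean
  inter-mutation distance ≤ 1 kb), and a permutation test for enrichment
  of mutations in the terminal windows of chromosomes.
* **Cohort statistics**: tumor mutational burden per megabase, class
  proportion tables with explicit denominators, Pearson age–burden
  correlation, and driver mutual exclusivity with an exact Fisher test.

Because WGS cohorts of this kind are not freely redistributable, the
package ships a first-class **synthetic cohort generator**: a seeded
reference genome (N-gap "telomeres", low-complexity tracts, multi-exon
genes on both strands including designated driver loci), planted truth
mutations drawn from signature mixtures with kataegis clusters and
chromosome-terminal bias, and emulated per-caller VCFs with realistic
false positives plus matched-normal panels. Every analysis stage can
therefore be exercised — and scored against known truth — on a desk-scale
genome in seconds.

## Worked example

```r
library(somacohort)

cfg <- cohort_config(
  n_acp = 4, n_pcp = 3, mean_snv = 120, mean_indel = 10,
  chrom_lengths = c(chr1 = 500000L, chr2 = 400000L),
  kataegis_spec = data.frame(chrom = "chr1", center = 250000L,
                             n = 8L, span = 3000L),
  seed = 7)
res <- run_pipeline(cfg, out_dir = "cohort_report")
```

The run logs each stage:

```
reference: 2 chromosomes, 0.90 Mb, 36 mask tracts
truth: 1042 variants in 7 samples
callers: 3131 tumor records (1090 injected FPs), 167 normal records
panel of normals: 106 sites from 7 normals
filter: 2015 merged calls -> 1023 retained
annotate: 13 exonic / 14 intronic / 996 intergenic
spectrum: 7 sample spectra, 965 pooled SNVs
signatures: fitted 7 samples against 5 signatures
kataegis: 16 events
terminal enrichment: observed 0.346 vs expected 0.101 (p = 0.000999)
report: mean TMB 153.175 SNV / 9.206 InDel per Mb; filter F1 0.987
```

Most planted mutations are intergenic (97.4%), the filter recovers the
truth set with precision 0.996 / recall 0.978 against the injected caller
noise, mutations concentrate in the chromosome-terminal windows (observed
fraction 0.346 vs 0.101 expected under a uniform null, permutation
p ≈ 0.001), and the planted 8-mutation cluster at chr1:250 kb is detected:

```r
res$kataegis[1, ]
#>   chrom  start    end n_mutations mean_imd sample_id
#> 1  chr1 249432 254552           9      640     ACP01

res$exclusivity
#> exon3_driver: ACP 75.00%, PCP 0.00% (Fisher p = 0.143)
#> v600e_driver: ACP 0.00%, PCP 66.67% (Fisher p = 0.143)

res$correlation
#> Pearson r = 0.887, p = 0.007753 (n = 7)
```

Driver events segregate perfectly by subtype (the Fisher p is large only
because the example cohort has 7 samples; at the default 26-pair scale it
is < 0.001). The report bundle (`summary.json`, `per_sample.tsv`,
`proportions.tsv`, `exposures.tsv`, `kataegis.bed/tsv`, `log.txt`) lands
under `cohort_report/`.

The same pipeline runs from the shell:

```sh
exec/somacohort --synthetic --seed 7 --out cohort_report
```

Printed-count arithmetic works directly on published tallies, e.g.

```r
class_proportions(c(missense = 164, silent = 62, nonsense = 9, indel = 10),
                  denominator = 243)$percent
#> [1] 67.49 25.51  3.70  4.12
tmb(760)   # 0.246 mutations/Mb over the 3,088.27 Mb non-gap genome
tmb(39)    # 0.013
```

## Layout

```
R/            genome.R plant.R callers.R   synthetic cohort generator
              filter.R                     consensus + threshold filtering
              annotate.R                   gene model, region/effect calls
              spectrum.R signatures.R      6-class / 96-channel spectra
              refit.R                      signature exposure refitting
              kataegis.R                   rainfall, clusters, terminal test
              report.R pipeline.R          cohort statistics, orchestration
tests/        testthat suite with independent brute-force oracles
vignettes/    methods vignette (model, parameters, design choices)
exec/         command-line entry point
scripts/      acceptance.R
inst/extdata/ bundled synthetic signature matrix (TSV)
```
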