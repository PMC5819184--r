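---
title: "Quantifying sex-biased transposable-element proliferation from male and female genome skimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sex-biased transposable-element proliferation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a dioecious plant with an XY sex-determination system, male and female
genomes differ by one chromosome: males carry X + Y where females carry
X + X. When the Y is large — in *Silene latifolia* it is the largest
chromosome of the complement, about 1.4 times the X — male genomes are a
few percent larger than female genomes, and the male-female difference
isolates the Y-X size contrast without any assembly. Low-coverage
whole-genome shotgun ("genome skimming") reads from one male and one
female per population are then enough to ask which repeat families drive
genome-size change, and whether they do so on the Y or away from it.

dioecyTE implements that inference chain end to end:

1. **Copy-number estimation** from reads uniquely assigned to
   transposable-element (TE) subfamily references
   (`assign_reads_unique()`, `copy_number()`, `genome_proportion()`).
2. **Sex statistics** across populations ("ecotypes"): genome-size
   differences, abundance versus genome-size correlations, X-chromosome
   density, copy-number variability (`sexstats` functions).
3. **A transmission simulator** that derives, and verifies by Monte
   Carlo, the neutral expectations for where a sex-limited TE
   accumulates (`expected_density_ratio()`, `simulate_transmission()`).
4. **A synthetic data generator** — genomes with a known TE catalog and
   paired-end reads — so that every stage is testable against ground
   truth without access to the original sequencing data
   (`te_reference()`, `genome_blueprint()`, `simulate_reads()`).
5. **An orchestrating pipeline** (`run_pipeline()`) producing a
   reproducible table bundle.

## The residency argument

At an even sex ratio, two of every three X copies in the population sit
in females, so an X chromosome spends 2/3 of generations in female
bodies; an autosome spends 1/2; a Y none. A TE lineage that transposes
only in the female germline, and picks its target chromosome in
proportion to length among the chromosomes present in its carrier,
therefore inserts into the X at

$$\frac{2/3}{1/2} = \frac{4}{3} \approx 1.33$$

times the per-bp rate of an autosome — and never into the Y. For a
male-limited element the ratios are (1/3)/(1/2) = 2/3 for the X and
1/(1/2) = 2 for the Y. `expected_density_ratio()` returns these closed
forms; `simulate_transmission()` re-derives them by explicit simulation
of Mendelian chromosome transmission (constant population size, discrete
generations, random mating, insertions pre-meiosis in the carrier sex,
no recombination and no pseudoautosomal region). The simulator seeds its
initial TE load on autosomes only — an ancestral autosomal load — and
because activity is multiplicative (new insertions per existing copy),
that seed is a vanishing fraction of the final counts after ~200
generations; density ratios are computed from final counts, and the Y:A
ratio of a female-limited element is exactly zero by construction.

## Copy numbers from coverage

Reads are subsampled to `p` percent of the 1C genome size
(`sample_reads()`), assigned uniquely to subfamily references, and the
per-subfamily summed aligned bases ("bedcov-style" coverage) are
normalized as

$$\mathrm{copies} = \frac{\mathrm{coverage\ [bp]}}{\mathrm{subfamily\ length\ [bp]}} \times \frac{100}{p}.$$

With reads drawn from a *diploid* individual at `p`% of 1C this literal
formula counts copies per 1C (the expected coverage of a subfamily with
c copies per 2C is (p/100)·c·len/2). The `scale = "per-2C"` option
multiplies by two. All downstream ratio statistics — in particular the
X-density formula — use only ratios of female to male copy numbers and
are invariant to this choice.

The X-density statistic for a subfamily with female copy number F and
male copy number M is

$$\left(\frac{F - M}{F}\right) \times \frac{2}{0.15},$$

where 0.15 is the X chromosome's share of haploid genome length: F - M
counts the copies on one X (the chromosome the male lacks), and the
scaling converts that share into a per-bp density relative to the
genome average. For a strictly female-limited subfamily with X:A density
4/3 and X at 15% of the genome the expected value is
(4/3)/(0.85 + 0.15·4/3) ≈ 1.27. The statistic is meaningless for
subfamilies with substantial Y-linked copy numbers (F - M then
undercounts the X), so the pipeline reports `NA` for subfamilies whose
copy-number variability flags Y accumulation, rather than a misleading
number.

## The aligner

The unique-assignment step is a deliberately explicit primitive rather
than a wrapper around an external mapper, so that its acceptance test
can compare it against an exhaustive brute-force oracle at identical
thresholds. Each mate is scored independently against every reference:
k-mer seeds (default k = 12) propose diagonals; the whole read is scored
ungapped on each candidate diagonal with match +1 / mismatch −1,
clipped at reference ends; the reverse complement is always tried. A
mate is assigned to the single best-scoring subfamily only if

* aligned fraction ≥ 0.80 of the read,
* identity ≥ 0.90 over the aligned span,
* best score exceeds the runner-up subfamily by ≥ 1 (ties never count
  as unique).

The thresholds make unique assignment well-posed on reference libraries
whose pairwise identity is below 70%, which `te_reference()` enforces at
generation time. Mates are treated independently (no pair rescue), and
coverage is the summed aligned bp of assigned mates.

Two numerical consequences matter for validation and are accounted for
in the tests:

* **Junction clipping.** A read straddling a TE boundary is assigned
  only if ≥ 80% of it lies inside the element, and then contributes only
  its overlap. The expected assigned coverage per copy of length
  `len` from reads of length `L` is `L(len − L + 1) + 2·Σ o` over
  overlaps o in [0.8L, L), i.e. a factor ≈ (len − 0.64L)/len of the
  naive `L·len` — a 2-3% haircut for 150 bp reads on 3-5 kb elements.
* **Scale.** Estimated copies are per 1C (see above); the synthetic
  truth tables count per 2C, so recovery tests compare against half the
  diploid truth.

## What the generator emulates, and what it does not

`paper_like_spec()` encodes the structural facts of the studied system
at desk scale: 11 autosome pairs plus XY; X close to 15% of 1C; Y
exactly 1.4× the X; male diploid genomes 2-4.5% larger than female;
seven ecotypes whose female genome sizes span 1.07-fold; nine TE
subfamilies covering the observed behaviour classes (active
female-limited and X-enriched at 4/3; male-biased with Y-linked copy
numbers that vary across ecotypes; silent; unbiased). The default total
1C is ~7-8 Mbp rather than ~2.8 Gbp; because every downstream formula
takes the true sampled fraction as a parameter, this scaling is exact
for the statistics, and the subsampled read yield is set to 100% of the
scaled 1C so that per-sample read counts (~25,000 pairs) are comparable
to the absolute read numbers a 0.75%-of-1C skim yields on a
gigabase-scale genome. The silent subfamily is deliberately sized large
(~14% genome proportion) so that its dilution trend across the
1.07-fold size range exceeds binomial counting noise — the same
consideration any skimming study faces when deciding which families are
quantifiable.

Deliberate simplifications, chosen for testability:

* TE insertions never overlap or nest; truth tables are therefore
  unambiguous. Real genomes nest LTR retrotransposons heavily.
* Chromosome backbones are i.i.d. random sequence (GC 0.36), so there
  are no segmental duplications, satellites or organellar insertions to
  cross-react with the references; real backbones inflate unassigned
  (not misassigned) reads.
* Reads carry uniform substitution errors only (default 0.2%/base,
  constant Q30 qualities, no indels) — coverage statistics, not variant
  calls, are the target. Read length defaults to 150 bp (not 300 bp) to
  keep desk-scale runtimes.
* Coordinates are 0-based half-open; strands are recorded but coverage
  is strand-agnostic.

Passing tests on these synthetics demonstrate that the estimators
recover a known truth under the model's assumptions; they do not
demonstrate robustness to nested repeats, library-prep bias, or
reference incompleteness in real data.

## Numerical and design choices

* **Uniform placement** of insertions uses a sorted-gaps construction
  (sample the free space, then shift by cumulative element lengths);
  adjacent elements (zero gap) are allowed.
* **Subsampling** is by read pair (never splitting mates), hitting the
  bp target within one pair; requesting more than is available is an
  error that states the achievable fraction.
* **Degenerate inputs**: zero requested pairs yield a valid empty FASTQ
  with a warning; an empty read set yields all-zero coverage records;
  silent mode has no defined density ratio and errors; zero-variance
  vectors error in `pearson_with_p()`.
* **Dispersion metric**: both SD and CV are reported per sex; CV is the
  headline male-female comparison because male means carry the ~3-4%
  Y-driven offset, and the Y-polymorphism flag is
  `CV_male >= CV_female`.
* **Multiple testing**: raw two-sided p values plus Benjamini-Hochberg
  adjusted values; no hard-coded significance threshold.
* **Determinism**: every stochastic function takes an explicit seed,
  restores the caller's RNG state, and derives per-sample child seeds
  from the run seed, so a fixed spec + seed reproduces every table
  byte-for-byte. Problem sizes used by the validation suite — 20
  replicates × 200 generations for the transmission cross-check, ~2,000
  read pairs for per-family recovery, 75,000 pairs per sex for the
  X-density check, the full 7-ecotype run for the correlation signs —
  were chosen from standard-error arithmetic so that each assertion has
  a ≥3σ margin.

## Worked example

```r
library(dioecyTE)

spec <- paper_like_spec(seed = 1)
report <- run_pipeline(spec, out_dir = "report")
summary(report)

# closed-form and simulated residency expectations
expected_density_ratio("female_limited")
simulate_transmission(8, 200, "female_limited", activity = 0.05, seed = 1)
```

## Known limitations

* The X-density statistic assumes negligible Y-linked copies and no
  pseudoautosomal exchange; the pipeline flags, but cannot correct,
  violations.
* Unique assignment discards reads that map ambiguously between closely
  related subfamilies; libraries with pairwise identity above ~70%
  undercount both relatives.
* The transmission simulator models neither recombination nor selection;
  it is an oracle for the neutral residency argument, not a population
  genetics engine.
* Copy numbers from coverage are relative to the reference length of a
  single exemplar sequence; internal deletions or solo LTRs in real
  copies bias counts downward.
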