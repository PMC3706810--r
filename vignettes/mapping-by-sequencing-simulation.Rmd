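---
title: "Simulating mapping-by-sequencing experiments with popseqsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mapping-by-sequencing experiments with popseqsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popseqsim)
```

## The problem

Mapping-by-sequencing locates a causal, mutagen-induced mutation by
sequencing a pool of phenotypically selected recombinant plants and scanning
for local skews in parental allele frequencies. Before running such an
experiment, a lab has to commit to a crossing scheme (outcross to a diverged
accession, or backcross to the isogenic progenitor), a number of backcross
generations, a pool size, and a sequencing depth — all of which trade money
and greenhouse time against mapping resolution. `popseqsim` answers these
design questions by forward simulation: it breeds virtual mutant populations
on a configurable recombination landscape, simulates pooled short-read
sequencing at marker resolution, and runs the same downstream analyses a
real experiment would use.

Everything operates on marker coordinates; no nucleotide sequence is ever
generated. That keeps a full simulated experiment (hundreds of plants,
hundreds of thousands of reads, analysis included) below a second.

## The meiosis model

Per chromosome and meiosis, the number of crossovers is drawn from a
three-category model with probabilities $(p_1, p_2, p_3)$ of zero, one, and
two-or-more crossovers. Category three is resolved to $2 + G$ crossovers
with $G$ geometric (continuation probability 0.1, a configurable
`geom_continuation`), so triple crossovers are rare, matching the rarity of
multiple-crossover chromatids in plant data. The expected realized count is
therefore $p_2 + p_3\,\bar k$ with $\bar k = 2 + q/(1-q)$, and
`synthesize_landscape()` inverts this identity exactly when asked for a
target mean.

Crossover positions follow a per-interval placement probability $p_{m_i}$
aligned with the marker map: the density within an interval of length
$l_i$ is $p_{m_i}/l_i$ per base pair. The first crossover of a meiosis is
drawn from this marginal density. Additional crossovers are placed at
gamma-distributed distances from the previous one in *normalized genetic
coordinates* (the cumulative placement probability), modelling crossover
interference: with shape $s$ the coefficient of variation of spacings is
$1/\sqrt{s}$. Defaults are shape 2 and a scale that sets the mean spacing to
one third of the chromosome's genetic length (the expected spacing of two
uniform points). A gamma draw past the chromosome end is redrawn up to 20
times and then placed uniformly in the remaining genetic interval; with the
default parameters this fallback is rare. Interference is applied between
every successive pair of crossovers, not only the first two, and can be
disabled (`interference = FALSE` in `simulation_plan()`), which makes all
placements i.i.d. from the marginal density.

Two modelling simplifications are deliberate: the simulator works at the
gamete level (no four-strand chromatid bookkeeping, no obligate chiasma) and
there is no gene conversion. Both could bias fine-scale interference
statistics but are immaterial at the marker resolution the analyses use.

### Chromosome ends

Placement frequencies are supplied per marker (entry $i$ covers the
half-open interval from marker $i-1$ to marker $i$; entry 1 runs from the
chromosome start). The region beyond the outermost marker has no supplied
frequency; the simulator appends a terminal interval weighted by the last
interval's per-base-pair rate, then renormalizes. Marker maps whose last
marker sits at the chromosome end therefore reproduce the supplied
frequencies exactly; for synthetic quasi-uniform maps the appended tail
carries about half a marker spacing of mass.

## Crossing schemes and pools

The mutagenized founder is homozygous for `n_mutations` uniformly placed
mutations (defaults bracket chemical-mutagenesis loads: 700 or 1400 on a
~119 Mb genome), one of which is causal; the phenotype is recessive
(mutant iff causal genotype 2).

* **Outcross**: founder × diverged accession, self the F1. Natural
  polymorphisms (the marker map) and the mutations segregate in the F2.
* **Backcross**: `backcross_rounds` successive crosses of a causal-allele
  carrier to the isogenic parent, then one selfing. Only the induced
  mutations segregate. The plant carried into each round is a heterozygous
  carrier: crosses to the recurrent parent cannot produce homozygotes, and
  requiring one causal allele is the weakest condition that keeps the
  mutation in the lineage. Multi-parent designs (`n_parent_siblings`) breed
  independent carrier lineages that contribute equal F2 shares.

Pools are drawn from the phenotypic mutants of an F2; mis-scored plants are
real phenotypically wild-type siblings of the same population (a natural
2:1 heterozygote:wild-type mixture), substituted in at
`round(misscore_rate * n_mutants)` positions. Sampling true wild-type
siblings — rather than synthetic genotypes — is the biologically faithful
contamination model.

## Sequencing model

Coverage at the sequenced loci is one multinomial draw of `m` total reads
with probabilities proportional to per-marker normalization weights
(observed coverage relative to the genome average; weight 1 for mutation
loci absent from the marker map). `m = round(coverage × loci)` converts a
genome-wide coverage target to reads at marker resolution. Reads at a locus
are assigned by a trinomial with probabilities
$(a_1 (1-s),\; a_2 (1-s),\; s)$ — mutant allele, other allele, sequencing
error — where $a_1$ is the pool's true mutant-allele frequency and
$s = 0.003$ a deliberately conservative error rate. The trinomial is often
written with probabilities $[a_1, a_2, s]$, which is improper since
$a_1 + a_2 = 1$; scaling the allele terms by $(1-s)$ preserves the error
mass exactly.

What becomes of an error read is not specified by the threshold model it
feeds, so both natural readings are implemented: the default `"split"` rule
assigns each error read to either parental allele with probability 1/2 (so
a fixed locus shows a wild-type read fraction of $s/2$); the `"flip"` rule
sends every error read to the allele it did not come from (wild-type
fraction $s$ at a fixed locus). The choice is a `seq_params()` switch and
the default is a package decision, not a claim about any reference
implementation.

Target-enrichment mode restricts reads to loci flagged `enriched` and
spreads the read budget over them alone; everything else gets coverage
zero, emulating capture sequencing of large-genome crops.

## Homozygous-mutation calling (backcross analysis)

A mutation is called homozygous in the pool iff its observed mutant read
frequency exceeds both

* the genotype-frequency threshold $g_f = 1 - (2m + 1)/(2n)$ for a pool of
  $n$ mutants of which $m$ are assumed mis-scored — the frequency at which
  one extra wild-type chromosome beyond the assumed contamination would
  sit; and
* the read-frequency threshold $r_f = 1 - e - 1/c_p$ at coverage $c_p$ —
  the frequency observed when one read samples a non-mutant chromosome or
  is an error.

At $c_p = 1$ the read threshold is vacuous (negative), so calling requires
`min_coverage` (default 2). `m_mis` defaults to 0 and must be set
explicitly by experiments that study mis-scoring; `run_replicate()` sets it
to the pool's actual mis-scored count.

## Confidence mapping intervals (outcross analysis)

The interval statistic aggregates observed mutant-allele frequencies over a
sliding window of `window` markers (coverage-weighted) and asks, for every
position, whether its window frequency is compatible with the peak's: the
Gaussian likelihood-ratio
$(f_\text{peak} - f(x))^2 / (\mathrm{se}^2_\text{peak} + \mathrm{se}^2(x))$
is compared with the $\chi^2_1$ quantile at the confidence level (default
0.99), and the interval is the maximal contiguous run around the peak below
that cut. The variance of a window frequency has a read-sampling part
$f(1-f)/C_w$ *and* a pool-sampling part $f(1-f)/(2n)$: all markers in a
window are read from the same $2n$ pooled chromosomes, so the pool part
does not average away with window size. This is exactly why mapping
resolution is limited by the number of recombinants rather than by
coverage, and the simulated sweeps reproduce that interplay.

An earlier construction — per-marker plug-in binomial log-likelihood ratios
against $a_1 = 0.5$, window-mean smoothed — was implemented and rejected:
plug-in likelihood rewards small-pool sampling noise and measures deviation
from 0.5 (which saturates across the whole linked region) rather than
localization, and in simulation it produced *larger* intervals for larger
pools, inverting the best-established experimental-design result. The
present statistic treats the peak and candidate estimates as independent,
ignoring their positive correlation; that makes intervals conservative
(wider), which is the right direction for a procedure whose contract is to
contain the causal mutation at no less than the nominal rate. Calibration
is enforced by test: across 200 outcross replicates (100 mutants, 25×) the
causal mutation must lie inside the 99% interval in at least 97% of
replicates.

Ties at the peak break to the leftmost position. If the smoothed peak
frequency stays below `min_peak_freq` (default 0.75, halfway between the
segregating 0.5 and fixation regimes with margin), the data are flagged
uninformative and the whole genome is returned. The default window
(`"auto"`) is an odd number near one fifth of the per-chromosome marker
count — wide enough to suppress read noise at 5–15×, narrow relative to the
linkage-decay scale of typical selected pools.

## Foreground genome and direct sequencing

`foreground_fraction()` returns the base-pair share of a diploid genome
derived from the mutagenized founder. For *unconditioned* backcrossing each
cross halves the expected foreground, giving the classic recurrent-parent
fraction $(2^{n+1}-1)/2^{n+1}$ after $n$ rounds; `unselected_backcross()`
realizes exactly this protocol, and the package's headline foreground
percentages for BC2 and BC3 (about 12.5% and 6.25% on the Arabidopsis-like
landscape) are computed from it.

Phenotype selection changes this picture drastically.
`foreground_backcross_study()` runs the fully selected protocol — carrier
maintenance each round plus selection of causal-homozygous F2 mutants — and
shows mean foregrounds far above the unconditioned expectation (well above
14% for BC2F2 at one crossover per chromosome per meiosis, against an
unconditioned 12.5%).
This is classic linkage drag: conditioning on the causal locus retains a
founder segment of the order of 50–100 cM around it after two to three
backcrosses. Reports that selected backcross material sits only fractions
of a percentage point above the theoretical recurrent fraction are
consistent with the unconditioned protocol, not with selection at the
causal locus; both protocols are exported so users can quantify the gap on
their own landscapes.

## Single-end versus paired-end reads

`compare_se_pe()` draws 100,000 random alignments per read length and mode,
with paired-end inserts fixed at exactly three times the read length (no
insert-size variance), and scores an alignment informative when a marker
falls inside the read — or inside either mate, counted once, since mates
share one genetic background and cannot contribute twice to an
allele-frequency estimate. Markers inside the unsequenced insert gap do not
count. Multi-mapping is modelled as an exclusion mask supplied alongside
the marker map; excluded draws stay in the denominator but are never
informative. Absolute informative-read excesses measured on real genomes
depend on the species' repeat structure and are out of scope; the
simulator's contract is the geometry and the counting rules, verified
against an exhaustive all-start-positions oracle on toy genomes.

## Synthetic landscapes and what passing tests show

`synthesize_landscape()` generates quasi-uniformly spaced markers and either
uniform or hotspot-peaked placement frequencies; presets provide
Arabidopsis-like (5 chromosomes, ~119 Mb, mean 1 crossover per chromosome
per meiosis), rice-like (12 chromosomes, ~380 Mb, mean 1.2) and barley-like
(7 chromosomes, ~4.6 Gb, mean 0.8, enrichment sequencing by default)
conditions. These synthetic inputs emulate the *structure* of real
landscapes — crossover-count frequencies, placement heterogeneity,
interference — but not any particular empirical map, marker set, or
coverage bias profile. Consequently the package's tests verify model
properties, calibration, and the direction and saturation of
pool-size/coverage effects; absolute interval sizes and CAM counts from
experiments on real landscapes are reproducible only by supplying the
corresponding landscape and marker files to `load_landscape()`.

## Problem sizes and reproducibility

The shipped studies use desk-scale sizes chosen as a package default:
100–150 synthetic markers per chromosome, 100–200 replicates per
pool-size/coverage cell (the sweep default is 500, matching full-scale
practice, and the replicate count is always recorded in outputs), 3000–8000
individuals for foreground studies. Every randomized routine draws its
seeds through `child_seed()`, a deterministic integer mixer, so a sweep is
a pure function of its configuration and root seed; replicate `i` of cell
`(pool, coverage)` is reproducible in isolation.

```{r example, eval = FALSE}
cfg <- sweep_config(scheme = "backcross", pool_sizes = c(10, 20, 40),
                    coverages = c(15, 50), replicates = 100, seed = 1)
sw <- run_sweep(cfg)
sw$summary
```

## Known limitations

* No fitness or viability differences, no de-novo mutation during breeding,
  no residual heterozygosity in the founder.
* No read-level simulation: no base qualities, indels, or
  alignment artifacts beyond the weight landscape and the exclusion mask.
* The three-category crossover model cannot express means above
  $\bar k$ · (feasible tail mass); with defaults the ceiling is ~1.33
  crossovers per chromosome per meiosis (raise `tail_mass` for more).
* Interval endpoints snap to marker positions; with sparse maps the
  reported length under-resolves the true uncertainty by up to one marker
  spacing on each side.
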