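---
title: "Same-species spike-in normalization: model, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Same-species spike-in normalization: model, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snipchip)
```

## The problem

ChIP-seq signal tracks are internally normalized (per-sample sequencing
depth), so they cannot be compared *between* samples: a mutant that binds a
quarter as much target protein everywhere produces a track
indistinguishable from wild type after conventional scaling. Spike-in
normalization solves this by adding a constant proportion of foreign
chromatin to every sample and using its recovered signal as an internal
ruler. `snipchip` implements the same-species variant of this idea: the
spike-in cells come from a second strain of the *same* species, and reads
are assigned to their genome of origin using the strains' intra-species
SNPs. Because the spike-in shares the test organism's proteome, the
approach works for any target with a ChIP-grade antibody — including
post-translational modifications — without epitope tags or cross-species
antibody compatibility assumptions.

## Model

Let a sample contain a fraction $s$ of spike-in cells and $1-s$ of test
cells, and let $A$ denote the per-cell amount of chromatin-bound target in
the test condition, expressed in units of the spike-in's per-cell amount
($A_{spike} \equiv 1$). For each sequenced sample, classification yields
aggregate signals $C_{endo}$ and $C_{spike}$ for the two genomes, and the
quotient

$$Q = C_{spike} / C_{endo}.$$

For the non-immunoprecipitated **input** sample, $Q_{Input}$ measures the
cell mixture itself: the spike-in percentage of the sample is
$100 \cdot Q_{Input} / (1 + Q_{Input})$, i.e. the nominal mixing
percentage corrected for pipetting and counting error. For the **ChIP**
sample, $Q_{ChIP}$ additionally reflects the target abundance: more test
target means relatively fewer spike-in reads. The per-condition
normalization factor is

$$N_f = Q_{Input} / Q_{ChIP},$$

and, in the idealized sampling model implemented by the simulator
(`expected_values()`),

$$\mathbb{E}[N_f] \;=\; \frac{A \, W_{test} \, L_{spike}}{W_{spike} \, L_{test}}
 \;\xrightarrow{\text{matched genomes/profiles}}\; A,$$

where $L$ are genome sizes and $W$ total binding-profile weights. Dividing
a condition's $N_f$ by the reference condition's $N_f$
(`relative_level()`) yields the wild type-normalized level — a
semi-quantitative measure of relative target amount. Multiplying a
condition's signal track by $N_f$ (`apply_norm_factor()`), usually after
per-million scaling (`spmr_scale()`), puts all conditions on one
spike-in-anchored scale.

Note what cancels in $Q$: sequencing depth (both counts scale together),
fragment-size extension, and any constant per-sample efficiency. This is
why the method is robust to unbalanced sequencing depths, which the
subsampling analysis (`nf_subsample_grid()`) verifies.

## Read classification

Reads are aligned to a **hybrid reference** formed by concatenating the
two assemblies (`build_hybrid_reference()`; contigs named
`<strain>_<chrom>`). Classification follows the perfect-match rule: a read
is kept only if its sequence occurs at **exactly one** position (either
strand) in the hybrid. A read spanning no SNP occurs in both genomes and
is discarded as ambiguous; a read spanning at least one SNP with an exact
match is uniquely placeable and its contig decides the genome of origin.
Under error-free simulation this cannot mis-assign a read, which the test
suite asserts as an exact zero. The in-package engine
(`build_exact_index()`) enumerates all read-length windows of both strands
into a hash-joinable table; the real-data route ingests per-contig counts
from an external aligner run at zero-mismatch settings
(`counts_from_contig_table()`).

The price of same-species spike-in is information loss, not bias: at the
published regime (~0.7% divergence, 100-bp reads) the probability that a
window contains at least one SNP is $1-(1-d)^{100} \approx 50\%$, and
`assignable_fraction()` measures the realized ceiling (uniqueness can only
remove windows). Tolerating sequencing errors is deliberately out of
scope: an error turns a read into either an unmapped sequence (signal
loss, the dominant outcome) or — if it lands exactly on the read's only
SNP — a valid read of the other genome. The simulator's optional
`error_rate` exists to quantify that loss; the suite checks cross-calls
stay below $10^{-3}$ at a 1% error rate.

## The four estimators

`C_endo`/`C_spike` can be (1) total assigned read counts (`read_count`),
or mean pileup scores over (2) all positions (`pileup_all`), (3) SNP
positions (`pileup_snp`), or (4) SNP positions inside signal peaks
(`pileup_snp_peaks`), the last excluding background-only regions.
For broadly distributed targets all four give concordant $N_f$ (the
acceptance suite requires pairwise agreement within 5%); `read_count` is
the default because it is the simplest and needs no per-base tracks. The
peak-restricted variant depends on the peak definition supplied; any BED
is accepted (`read_bed()`), and only a naive threshold caller is bundled
(`call_peaks_naive()`) to make fixtures self-contained.

Pileups are built at raw read length without fragment extension: a
constant extension factor multiplies both genomes' coverage equally and
cancels in $Q$. SPMR-style scaled tracks from this package therefore
differ from fragment-extended tracks of external callers by a smoothing
factor, which is documented rather than imitated.

## The synthetic world

`sim_config()` states the world the package is validated in; defaults are
the published regime, fixed once and not revisited:

| parameter | default | rationale |
|---|---|---|
| divergence | 0.007 | the strain pair's ~76,000 SNPs over a 12 Mb genome |
| spike_fraction | 0.20 | the standard 80%:20% cell mix |
| read_length | 100 | the protocol's recommended minimum read length |
| n_reads | 200,000 | desk-scale depth at which Monte-Carlo error ≪ tolerances |
| n_chromosomes × chrom_length | 2 × 100 kb | desk-scale genome preserving per-chromosome structure |
| n_peaks × peak_width | 24 × 2 kb | broad binding, ≥ 10 SNPs per peak in expectation |
| enrichment_fold | 8 | moderately enriched broad peaks |
| error_rate | 0 | perfect-match alignment makes errors a pure loss term |

The generator draws the test genome i.i.d. uniform, substitutes each base
independently with probability `divergence` to produce the spike genome
(so the SNP map is exactly known), places non-overlapping uniform-weight
peaks shared by the colinear pair, and samples reads by the mixture model
above. Every sample has its own RNG stream derived from `(seed,
condition, role)`, so adding a condition never changes existing samples.

What the simulator does *not* emulate: indels and structural variation
between the strains (real assemblies need an externally derived SNP VCF),
GC and mappability bias, PCR duplicates, fragment-length distributions,
and chromatin accessibility structure in the input. A green test therefore
establishes the *statistical* correctness of classification and estimation
under the stated sampling model — not robustness to alignment artifacts of
real divergent assemblies.

## Numerical and design choices

- **Coordinates**: 0-based half-open everywhere internally; conversion at
  I/O boundaries only (VCF 1-based, BED/bedGraph 0-based).
- **Expected values**: $L$ and $W$ are evaluated over valid read start
  positions ($L - k + 1$ per chromosome), matching the read sampler
  exactly; the difference from whole-chromosome totals is $O(k/L)$ and
  cancels entirely for matched pairs.
- **Palindromic reads** match one locus on both strands, count as two
  placements, and are discarded as ambiguous — mirroring aligner
  multi-mapping behavior for this degenerate case.
- **Naive peak caller scaling**: the input track is scaled by the ratio of
  median coverages (background level) rather than total mass. For broadly
  bound targets, peak reads are a large share of ChIP mass, so mass
  scaling would deflate enrichment below any useful threshold. A `max_gap`
  option bridges the zero-coverage holes that SNP-assigned reads leave
  between widely spaced SNPs; peak edges beyond the outermost SNP are
  invisible in principle, so recovered boundaries are fuzzy at the
  ~100 bp scale.
- **Titration linearity**: the ChIP-vs-input spike-fraction relationship
  is exactly linear only when the condition's abundance matches the
  spike-in ($A = 1$); for $A \ne 1$ the exact map is
  $s \mapsto s/(A + (1-A)s)$, mildly concave. The linearity acceptance
  test therefore runs at $A = 1$, and $N_f$ recovery is asserted at
  $A = 0.25$ where the criterion is attainable (±10% at fractions ≥ 15%).
- **Subsample grid sizes** (acceptance): 0.2–1.0 M reads from 1 M-read
  parents, fixed a priori from the closed-form Monte-Carlo CV
  $\mathrm{CV}^2 \approx \sum_{samples} \overline{(1/C_{spike} + 1/C_{endo})}
  \approx (1.2\%)^2$, inside the 2% criterion by design rather than
  tuning.
- **Degenerate inputs**: $C_{endo} = 0$ and $Q_{ChIP} = 0$ are errors
  (never silent infinities); $C_{spike} = 0$ yields $Q = 0$ with a
  warning; estimated spike-in percentage below 15% warns (noise inflates
  levels there), matching the titration finding.
- **Replicates**: condition replicate $N_f$ values are divided by the mean
  reference $N_f$; levels are reported as mean ± SD.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, abundance = c(wildtype = 1, mutant = 0.25))
world <- sim_world(cfg)
hybrid <- build_hybrid_reference(world$test, world$spike)
index <- build_exact_index(hybrid, cfg$read_length)

conditions <- lapply(c(wildtype = "wildtype", mutant = "mutant"), function(cid)
  list(chip = assign_reads(simulate_reads(cfg, cid, "ChIP", world)$reads, index),
       input = assign_reads(simulate_reads(cfg, cid, "Input", world)$reads, index)))
conditions$wildtype$reference <- TRUE

report <- normalize_experiment(conditions, snpmap = world$snpmap,
                               index = index, read_length = cfg$read_length)
report
```

The mutant's reported level recovers the simulated 25% within Monte-Carlo
tolerance; the acceptance suite repeats this for levels 0.10–0.75 over
five seeds.

## Known limitations

- Real divergent assemblies are not colinear; `derive_snp_map()` refuses
  them and a SNP VCF from whole-genome alignment must be supplied.
- Sparsely binding targets (e.g. transcription factors) violate the
  broad-binding assumption: most SNPs then carry background signal and the
  normalization factor loses sensitivity. This mirrors the method's
  documented scope.
- The statistical uncertainty of $N_f$ beyond replicate SD (error
  propagation, confidence intervals) is out of scope.
- The exact-match engine targets desk-scale genomes (tens of Mb); it is an
  executable specification of "perfect match, unique placement", not a
  replacement for a production aligner on full datasets.
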