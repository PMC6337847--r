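# snipchip

Same-species spike-in normalization for ChIP-seq, via SNP-based read
classification.

## The problem this package addresses

ChIP-seq tracks are normalized per sample, so they cannot quantify
*between-sample* changes: a mutant with uniformly reduced binding of a
chromatin protein looks identical to wild type after conventional
scaling. Spiking every sample with a constant proportion of cells from a
**second strain of the same species** provides an internal ruler: reads
are assigned to the test or the spike-in genome through the strains'
intra-species SNPs (for the classic budding-yeast pair, ~76,000 SNPs at a
median spacing of 70 bp), and the recovered spike-in signal anchors all
conditions on one scale. Because the spike-in shares the organism's
proteome, this works for any target with a ChIP-grade antibody, including
histone modifications — no epitope tags, no cross-species antibody
assumptions.

The package is aimed at epigenomics analysts who want (a) the
normalization-factor computation for real experiments (via per-contig
count tables from any zero-mismatch aligner), and (b) a fully simulated,
ground-truthed environment in which every stage of the method is testable.

## The statistic at its core

With a fraction *s* of spike-in cells mixed into each sample, each
sequenced sample yields aggregate signals C<sub>endo</sub> and
C<sub>spike</sub> for the two genomes, and

> **Q** = C<sub>spike</sub> / C<sub>endo</sub>

The input (non-immunoprecipitated) sample's Q measures the realized cell
mixture — the spike-in percentage is 100·Q<sub>Input</sub>/(1 +
Q<sub>Input</sub>) — while the ChIP sample's Q additionally reflects
target abundance. The per-condition normalization factor

> **Nf** = Q<sub>Input</sub> / Q<sub>ChIP</sub>

equals (in expectation) the condition's per-cell target amount relative
to the spike-in; Nf ratios against a reference condition give wild
type-normalized levels, and multiplying a condition's track by Nf yields
comparable, spike-in-scaled profiles. Sequencing depth, fragment
extension, and per-sample efficiencies cancel in Q — the robustness
analyses in this package verify exactly that.

C<sub>endo</sub>/C<sub>spike</sub> can be assigned read counts (default)
or mean pileup scores over all positions, SNP positions, or SNPs inside
peaks; the four estimators agree within 5% on broadly bound targets.

## Worked example

Simulate a wild type plus a mutant carrying 25% of the wild-type target
amount, both sequenced as 80%:20% test:spike-in mixtures, then run the
full workflow:

```r
library(snipchip)

cfg <- sim_config(seed = 1, n_reads = 100000L,
                  abundance = c(wildtype = 1, mutant = 0.25))
world <- sim_world(cfg)
world$snpmap
#> SnpMap: 1,414 SNPs on 2 chromosome(s), divergence 0.00707

hybrid <- build_hybrid_reference(world$test, world$spike)
index <- build_exact_index(hybrid, cfg$read_length)

conditions <- lapply(c(wildtype = "wildtype", mutant = "mutant"), function(cid)
  list(chip  = assign_reads(simulate_reads(cfg, cid, "ChIP",  world)$reads, index),
       input = assign_reads(simulate_reads(cfg, cid, "Input", world)$reads, index)))
conditions$wildtype$reference <- TRUE

conditions$wildtype$chip
#> AssignmentResult: 100,000 reads | test 41,239 (41.2%), spike 10,312 (10.3%),
#>   ambiguous 48,449, unmapped 0

report <- normalize_experiment(conditions, snpmap = world$snpmap,
                               index = index, read_length = cfg$read_length)
report
#> NormalizationReport [read_count], reference 'wildtype':
#>   wildtype     Nf = 1.002  level = 100.0%  spike-in = 20.0%
#>   mutant       Nf = 0.2475  level = 24.7%  spike-in = 19.9%
```

Reading the output: about half the reads span no SNP and are discarded as
ambiguous (the expected cost of same-species spike-in at 0.7% divergence
with 100-bp reads); the input samples recover the 20% spike-in mix; and
the mutant's wild type-normalized level, 24.7%, recovers the simulated
25% within Monte-Carlo tolerance — the quantitative change that
depth-normalized ChIP-seq alone cannot see.

For real data, align reads to the concatenated hybrid FASTA with any
aligner at zero-mismatch/unique-placement settings, summarize per-contig
mapped counts (`samtools idxstats` layout), and feed the tables to
`counts_from_contig_table()` / `normalize_experiment()`.

A command-line front end covering the same workflow lives at
`inst/cli/snipchip.R` (subcommands `snpmap`, `classify`, `tracks`,
`simulate`, `normalize`).

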