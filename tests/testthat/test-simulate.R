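test_that("sim_config validates its stated world", {
  expect_error(sim_config(divergence = 0.2), "divergence")
  expect_error(sim_config(spike_fraction = 0), "spike_fraction")
  expect_error(sim_config(spike_fraction = 1), "spike_fraction")
  expect_error(sim_config(abundance = c(1)), "named")
  expect_error(sim_config(n_peaks = 200L, peak_width = 2000L,
                          n_chromosomes = 1L, chrom_length = 100000L),
               "fit")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
})

test_that("zero divergence yields identical genomes and an empty SNP map", {
  cfg <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 5000L,
                    divergence = 0, n_peaks = 0L)
  gp <- simulate_genome_pair(cfg)
  expect_identical(gp$test$chromosomes[[1]], gp$spike$chromosomes[[1]])
  expect_equal(nrow(gp$snpmap$records), 0L)
})

test_that("genome pair generation is deterministic and truth-consistent", {
  cfg <- sim_config(seed = 12L, n_chromosomes = 2L, chrom_length = 8000L,
                    divergence = 0.01, n_peaks = 0L)
  a <- simulate_genome_pair(cfg)
  b <- simulate_genome_pair(cfg)
  expect_identical(a$test$chromosomes, b$test$chromosomes)
  expect_identical(a$snpmap$records, b$snpmap$records)
  # truth SNPs are exactly the positionwise differences
  expect_equal(derive_snp_map(a$test, a$spike)$records, a$snpmap$records)
})

test_that("binding profiles place non-overlapping peaks with the stated weights", {
  g <- strain_genome("T", c(chrI = random_dna_str(1000)))
  u <- simulate_binding_profile(g, n_peaks = 0L, peak_width = 100L,
                                enrichment_fold = 10, seed = 1L)
  expect_equal(u$profile$W, 1000)
  expect_equal(nrow(u$peaks$intervals), 0L)

  p1 <- simulate_binding_profile(g, n_peaks = 1L, peak_width = 100L,
                                 enrichment_fold = 10, seed = 1L)
  expect_equal(p1$profile$W, 900 + 1000)  # 900 background + 100 x fold 10

  w <- shared_world()
  iv <- w$peaks$intervals
  expect_equal(nrow(iv), 16L)
  # non-overlap within chromosomes
  for (ch in unique(iv$chrom)) {
    d <- iv[chrom == ch][order(start)]
    if (nrow(d) > 1L) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_error(simulate_binding_profile(g, n_peaks = 11L, peak_width = 100L,
                                        enrichment_fold = 2, seed = 1L),
               "fit")
})

test_that("background_fraction rescales background weight to the requested share", {
  g <- strain_genome("T", c(chrI = random_dna_str(2000)))
  p <- simulate_binding_profile(g, n_peaks = 2L, peak_width = 200L,
                                enrichment_fold = 10,
                                background_fraction = 0.3, seed = 5L)
  w <- unlist(p$profile$per_chromosome)
  bg <- sum(w[w != 10])
  expect_equal(bg / sum(w), 0.3, tolerance = 1e-9)
})

test_that("input samples hit the expected spike read fraction", {
  # s = 0.5, equal lengths: symmetric by construction
  cfg <- sim_config(seed = 41L, n_chromosomes = 1L, chrom_length = 30000L,
                    divergence = 0.007, n_peaks = 0L, spike_fraction = 0.5,
                    n_reads = 20000L, abundance = c(wt = 1))
  w <- sim_world(cfg)
  sim <- simulate_reads(cfg, "wt", "Input", w)
  frac <- mean(sim$reads$truth_origin == "spike")
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("matched abundance gives Nf ~ 1 and reads are deterministic per seed", {
  cfg <- sim_config(seed = 8L, n_chromosomes = 1L, chrom_length = 30000L,
                    divergence = 0.007, n_peaks = 4L, peak_width = 1000L,
                    n_reads = 30000L, abundance = c(wt = 1))
  w <- sim_world(cfg)
  ev <- expected_values(cfg, "wt", w)
  expect_equal(ev$Nf, 1)
  expect_equal(ev$Q_input, 0.25)
  expect_equal(ev$Q_chip, 0.25)

  idx <- build_exact_index(build_hybrid_reference(w$test, w$spike), 100L)
  nf <- compute_Nf(
    compute_Q(with(assign_reads(simulate_reads(cfg, "wt", "Input", w)$reads, idx),
                   sample_counts("Input", C_endo, C_spike))),
    compute_Q(with(assign_reads(simulate_reads(cfg, "wt", "ChIP", w)$reads, idx),
                   sample_counts("ChIP", C_endo, C_spike))))
  expect_lt(abs(nf$value - 1), 0.1)

  r1 <- simulate_reads(cfg, "wt", "ChIP", w)$reads
  r2 <- simulate_reads(cfg, "wt", "ChIP", w)$reads
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$truth_origin, r2$truth_origin)
})

test_that("expected_values reduces to the abundance ratio on the matched world", {
  cfg <- shared_config()
  w <- shared_world()
  expect_equal(expected_values(cfg, "mutant", w)$Nf, 0.25)
  ev <- expected_values(cfg, "wildtype", w)
  expect_equal(ev$Q_input, 0.2 / 0.8)
  expect_equal(ev$Nf, 1)
  expect_error(expected_values(cfg, "nosuch", w), "abundance")
})

test_that("substitution errors cause signal loss, never mis-assignment", {
  cfg_err <- sim_config(seed = 61L, n_chromosomes = 1L, chrom_length = 30000L,
                        divergence = 0.007, n_peaks = 0L, n_reads = 15000L,
                        abundance = c(wt = 1), error_rate = 0.01)
  cfg_clean <- cfg_err; cfg_clean$error_rate <- 0
  w <- sim_world(cfg_clean)  # same genomes: error_rate plays no role in the world
  idx <- build_exact_index(build_hybrid_reference(w$test, w$spike), 100L)
  asg_err <- assign_reads(simulate_reads(cfg_err, "wt", "ChIP", w)$reads, idx)
  asg_clean <- assign_reads(simulate_reads(cfg_clean, "wt", "ChIP", w)$reads, idx)
  expect_gt(asg_err$n_unmapped, asg_clean$n_unmapped)
  # an error landing exactly on a read's SNP can flip it to the other
  # allele (mirroring real aligner behavior); such cross-calls must stay
  # rare at 1% error, and error-free reads must never cross (tested in
  # test-classify.R)
  sim <- simulate_reads(cfg_err, "wt", "ChIP", w)
  pr <- assign_reads(sim$reads, idx)$per_read
  assigned <- pr$call %in% c("test", "spike")
  n_cross <- sum(pr$call[assigned] != sim$reads$truth_origin[assigned])
  expect_lt(n_cross / nrow(pr), 1e-3)
})

test_that("the generator's peaks are recovered by the naive caller", {
  cfg <- shared_config()
  w <- shared_world()
  chip <- pileup_from_assignment(shared_assignment("wildtype", "ChIP")$assignment,
                                 100L, "test")
  input <- pileup_from_assignment(shared_assignment("wildtype", "Input")$assignment,
                                  100L, "test")
  # bridge the zero-coverage holes SNP-assigned reads leave between
  # widely spaced SNPs (~2x read length + median SNP spacing)
  called <- call_peaks_naive(chip, input, fold = 4, min_width = 200L,
                             max_gap = 300L)
  truth <- w$peaks$intervals
  # every truth peak detected, and >= 80% reciprocal overlap at the
  # peak-set level (SNP-free peak edges are invisible to assigned reads,
  # so per-peak boundaries are fuzzy by design)
  ov_per_peak <- vapply(seq_len(nrow(truth)), function(i) {
    tv <- truth[i]
    cand <- called$intervals[chrom == tv$chrom & start < tv$end & end > tv$start]
    if (!nrow(cand)) return(0)
    sum(pmin(cand$end, tv$end) - pmax(cand$start, tv$start))
  }, numeric(1))
  expect_true(all(ov_per_peak > 0))
  expect_gte(sum(ov_per_peak) / sum(truth$end - truth$start), 0.8)
  expect_gte(sum(ov_per_peak) /
               sum(called$intervals$end - called$intervals$start), 0.8)
})

test_that("write_fixture is reproducible byte for byte", {
  cfg <- sim_config(seed = 71L, n_chromosomes = 1L, chrom_length = 10000L,
                    divergence = 0.007, n_peaks = 2L, peak_width = 500L,
                    n_reads = 2000L, abundance = c(wt = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(cfg, d1)
  write_fixture(cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("test.fa", "spike.fa", "hybrid.fa", "snps.tsv",
                    "peaks.bed", "wt_chip.fastq", "wt_input.fastq",
                    "truth.json", "manifest.json") %in% files))
  for (f in setdiff(files, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # regeneration from the manifest's config is identical
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  args <- man$config[setdiff(names(man$config), "background_fraction")]
  args$abundance <- unlist(args$abundance)
  cfg2 <- do.call(sim_config, args)
  d3 <- withr::local_tempdir()
  write_fixture(cfg2, d3)
  expect_identical(readLines(file.path(d1, "wt_chip.fastq")),
                   readLines(file.path(d3, "wt_chip.fastq")))
})

test_that("a scaled-down run recovers a 0.25x abundance ratio", {
  cfg <- sim_config(seed = 83L, n_chromosomes = 1L, chrom_length = 50000L,
                    divergence = 0.007, n_peaks = 8L, peak_width = 1500L,
                    n_reads = 50000L, abundance = c(wt = 1, mut = 0.25))
  w <- sim_world(cfg)
  idx <- build_exact_index(build_hybrid_reference(w$test, w$spike), 100L)
  nf_of <- function(cid) {
    qi <- compute_Q(with(
      assign_reads(simulate_reads(cfg, cid, "Input", w)$reads, idx),
      sample_counts("Input", C_endo, C_spike)))
    qc <- compute_Q(with(
      assign_reads(simulate_reads(cfg, cid, "ChIP", w)$reads, idx),
      sample_counts("ChIP", C_endo, C_spike)))
    compute_Nf(qi, qc, cid)
  }
  lv <- relative_level(nf_of("mut"), nf_of("wt"))
  expect_lt(abs(lv$level - 0.25) / 0.25, 0.10)
})
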