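test_that("locate finds all exact occurrences in deterministic order", {
  hyb <- build_hybrid_reference(strain_genome("T", c(chrI = "ACGT")),
                                strain_genome("S", c(chrI = "ACGA")))
  idx <- build_exact_index(hyb, read_length_hint = NULL)

  hits <- locate(idx, "ACG")
  # forward occurrence at position 0 of each contig, plus any minus-strand
  # hits; counts must match the window-scan oracle exactly
  orc <- oracle_locate_counts(hyb, "ACG")
  expect_equal(nrow(hits), orc$total)
  expect_true(all(c("T_chrI", "S_chrI") %in% hits$contig))
  fwd <- hits[hits$strand == "+"]
  expect_equal(fwd$start0[fwd$contig == "T_chrI"], orc$fwd_pos$T_chrI)
  # deterministic ordering: contig order, then position, then + before -
  expect_identical(hits, hits[order(match(contig, hyb$info$contig), start0,
                                    strand == "-")])

  expect_equal(nrow(locate(idx, "TTTT")), 0L)
  expect_equal(nrow(locate(idx, "ACGTACGT")), 0L)  # longer than any contig
})

test_that("locate agrees with the naive window-scan oracle on random hybrids", {
  set.seed(5)
  t <- strain_genome("T", c(chrI = random_dna_str(5000)))
  s_seq <- strsplit(t$chromosomes[["chrI"]], "")[[1]]
  flip <- sample(5000L, 35L)
  s_seq[flip] <- vapply(s_seq[flip],
                        function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                        character(1))
  s <- strain_genome("S", c(chrI = paste(s_seq, collapse = "")))
  hyb <- build_hybrid_reference(t, s)
  idx <- build_exact_index(hyb, read_length_hint = NULL)

  for (k in c(21L, 30L)) {
    # queries: genuine windows (mostly present) + random (mostly absent)
    qs <- c(vapply(sample(5000L - k, 50L), function(p)
              substr(t$chromosomes[["chrI"]], p, p + k - 1L), character(1)),
            replicate(20, random_dna_str(k)))
    for (q in qs) {
      hits <- locate(idx, q)
      orc <- oracle_locate_counts(hyb, q)
      expect_equal(nrow(hits), orc$total)
      # placement invariant: the placed substring (reverse-complemented on
      # the minus strand) equals the query
      if (nrow(hits)) {
        for (i in seq_len(nrow(hits))) {
          sub <- substr(hyb$contigs[[hits$contig[i]]], hits$start0[i] + 1L,
                        hits$start0[i] + k)
          if (hits$strand[i] == "-")
            sub <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(sub)))
          expect_identical(sub, q)
        }
      }
    }
  }
})

test_that("assign_reads applies the unique-perfect-match rule", {
  # 60-bp chromosomes differing at one position (SNP at 30)
  base <- random_dna_str(60)
  v <- strsplit(base, "")[[1]]
  v[31] <- setdiff(c("A", "C", "G", "T"), v[31])[1]
  alt <- paste(v, collapse = "")
  hyb <- build_hybrid_reference(strain_genome("T", c(chrI = base)),
                                strain_genome("S", c(chrI = alt)))
  idx <- build_exact_index(hyb, 40L)

  reads <- read_set(
    c("snp_test", "snp_spike", "shared", "with_n", "absent"),
    c(substr(base, 11, 50),   # covers SNP, test allele
      substr(alt, 11, 50),    # covers SNP, spike allele
      substr(base, 1, 25),    # SNP-free: present in both genomes
      paste0(substr(base, 11, 49), "N"),
      random_dna_str(40)))
  res <- assign_reads(reads, idx)
  calls <- setNames(res$per_read$call, res$per_read$read_id)
  expect_identical(unname(calls[c("snp_test", "snp_spike", "shared", "with_n")]),
                   c("test", "spike", "ambiguous", "unmapped"))
  expect_equal(res$C_endo, 1L)
  expect_equal(res$C_spike, 1L)
  expect_equal(res$C_endo + res$C_spike + res$n_ambiguous + res$n_unmapped,
               nrow(res$per_read))
  # assigned reads carry exactly one placement
  pr <- res$per_read[call %in% c("test", "spike")]
  expect_false(anyNA(pr$start0))

  expect_error(assign_reads(reads[0L], idx), "empty")
})

test_that("error-free simulated reads are never assigned to the wrong genome", {
  for (role in c("Input", "ChIP")) {
    sa <- shared_assignment("wildtype", role)
    pr <- sa$assignment$per_read
    assigned <- pr$call %in% c("test", "spike")
    expect_gt(sum(assigned), 0L)
    expect_equal(sum(pr$call[assigned] != sa$reads$truth_origin[assigned]), 0L)
    n <- nrow(pr)
    expect_equal(sa$assignment$C_endo + sa$assignment$C_spike +
                   sa$assignment$n_ambiguous + sa$assignment$n_unmapped, n)
  }
})

test_that("counts_from_contig_table sums mapped reads by origin", {
  origin_of <- c(T_chrI = "test", S_chrI = "spike")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("T_chrI\t1000000\t800\t0", "S_chrI\t1000000\t200\t0",
               "*\t0\t5\t0"), tsv)
  expect_message(cnt <- counts_from_contig_table(tsv, origin_of), "ignored 1")
  expect_equal(cnt$C_endo, 800)
  expect_equal(cnt$C_spike, 200)

  only_test <- withr::local_tempfile(fileext = ".tsv")
  writeLines("T_chrI\t1000000\t900\t0", only_test)
  expect_warning(c2 <- counts_from_contig_table(only_test, origin_of),
                 "Q will be 0")
  expect_equal(c2$C_spike, 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("weird\t10\t5\t0", bad)
  expect_error(counts_from_contig_table(bad, origin_of), "recognizable")
})

test_that("an in-package assignment round-trips through the contig table", {
  sa <- shared_assignment("wildtype", "ChIP")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contig_table(sa$assignment, tsv)
  info <- sa$assignment$info
  cnt <- counts_from_contig_table(tsv, setNames(info$origin, info$contig))
  expect_equal(cnt$C_endo, sa$assignment$C_endo)
  expect_equal(cnt$C_spike, sa$assignment$C_spike)
})

test_that("assignable_fraction handles the degenerate and oracle cases", {
  # zero SNPs: nothing is assignable
  g <- strain_genome("T", c(chrI = random_dna_str(2000)))
  g2 <- strain_genome("S", g$chromosomes)
  hyb_same <- build_hybrid_reference(g, g2)
  m0 <- derive_snp_map(g, g2)
  expect_equal(assignable_fraction(hyb_same, m0, 50L), 0)

  # every position a SNP on a random genome: every window contains a SNP
  # and is unique with overwhelming probability
  shifted <- chartr("ACGT", "CGTA", g$chromosomes[["chrI"]])
  gs <- strain_genome("S", c(chrI = shifted))
  hyb_all <- build_hybrid_reference(g, gs)
  m_all <- derive_snp_map(g, gs)
  expect_equal(nrow(m_all$records), 2000L)
  expect_equal(assignable_fraction(hyb_all, m_all, 50L), 1)

  expect_error(assignable_fraction(hyb_all, m_all, 5000L), "shortest")
})

test_that("sampled assignable_fraction approximates full enumeration", {
  cfg <- sim_config(seed = 77L, n_chromosomes = 1L, chrom_length = 10000L,
                    divergence = 0.01, n_peaks = 0L)
  gp <- simulate_genome_pair(cfg)
  hyb <- build_hybrid_reference(gp$test, gp$spike)
  full <- assignable_fraction(hyb, gp$snpmap, 100L)
  sampled <- assignable_fraction(hyb, gp$snpmap, 100L, max_enumerate = 1,
                                 n_sample = 8000L, seed = 3L)
  expect_lt(abs(full - sampled), 0.02)
})

test_that("assignable_fraction is monotone in divergence and bounded by the SNP-window probability", {
  # nested substitution sets: higher divergence strictly contains lower
  set.seed(99)
  L <- 20000L
  base <- random_dna_str(L)
  v <- strsplit(base, "")[[1]]
  all_pos <- sample.int(L, round(L * 0.007))
  subs <- lapply(c(0.0001, 0.001, 0.007), function(d)
    all_pos[seq_len(round(L * d))])
  g <- strain_genome("T", c(chrI = base))
  # independent oracle: exact fraction of 100-bp windows containing a SNP
  snp_window_frac <- function(p) {
    covered <- logical(L - 100L + 1L)
    for (q in p) {
      lo <- max(1L, q - 99L); hi <- min(q, L - 99L)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    mean(covered)
  }
  fracs <- vapply(subs, function(p) {
    vv <- v
    vv[p] <- vapply(v[p], function(b) setdiff(c("A","C","G","T"), b)[1],
                    character(1))
    gs <- strain_genome("S", c(chrI = paste(vv, collapse = "")))
    hyb <- build_hybrid_reference(g, gs)
    assignable_fraction(hyb, derive_snp_map(g, gs), 100L)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # uniqueness can only remove windows: fraction <= exact SNP-window share
  for (i in seq_along(subs))
    expect_lte(fracs[i], snp_window_frac(subs[[i]]) + 1e-12)
})

test_that("FASTQ round-trip preserves reads", {
  sa <- shared_assignment("wildtype", "Input")
  fq <- withr::local_tempfile(fileext = ".fastq")
  sub <- sa$reads[1:500]
  write_reads_fastq(sub, fq)
  back <- read_reads_fastq(fq)
  expect_identical(back$read_id, sub$read_id)
  expect_identical(back$seq, sub$seq)
})
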