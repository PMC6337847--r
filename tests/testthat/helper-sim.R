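# Shared fixtures (memoised across test files) and independent oracles.
# Oracles deliberately avoid the code paths they check: direct vector
# scans, explicit position lists, closed-form normal equations.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  v <- get0(key, envir = .fixture_env, inherits = FALSE)
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .fixture_env)
  }
  v
}

# Moderate peaked world shared by several files: 2 x 60 kb at 0.7%
# divergence, 16 x 2 kb peaks (>= 10 SNPs per peak in expectation),
# 8-fold enrichment, 20% spike-in cells, wild type + one 0.25x condition.
shared_config <- function() sim_config(
  seed = 101L, n_chromosomes = 2L, chrom_length = 60000L,
  divergence = 0.007, n_peaks = 16L, peak_width = 2000L,
  enrichment_fold = 8, spike_fraction = 0.2,
  abundance = c(wildtype = 1, mutant = 0.25),
  read_length = 100L, n_reads = 100000L)

shared_world <- function() memo("world", function() sim_world(shared_config()))

shared_hybrid <- function() memo("hybrid", function() {
  w <- shared_world()
  build_hybrid_reference(w$test, w$spike)
})

shared_index <- function() memo("index", function()
  build_exact_index(shared_hybrid(), 100L))

# One classified sample per (condition, role), reused wherever counts or
# pileups are needed.
shared_assignment <- function(condition_id, role) {
  memo(paste0("asg_", condition_id, "_", role), function() {
    sim <- simulate_reads(shared_config(), condition_id, role, shared_world())
    list(assignment = assign_reads(sim$reads, shared_index()),
         reads = sim$reads, truth = sim$truth)
  })
}

# Hand-built AssignmentResult for pileup toys: `placements` is a
# data.frame with call/contig/start0 columns; `genome` maps chrom -> length
# per origin via the info table.
fake_assignment <- function(info, placements, read_length = NA_integer_) {
  per <- data.table::data.table(
    read_id = sprintf("r%03d", seq_len(nrow(placements))),
    call = placements$call,
    contig = placements$contig,
    start0 = as.integer(placements$start0),
    strand = "+")
  structure(list(
    per_read = per,
    C_endo = sum(per$call == "test"),
    C_spike = sum(per$call == "spike"),
    n_ambiguous = sum(per$call == "ambiguous"),
    n_unmapped = sum(per$call == "unmapped"),
    info = data.table::as.data.table(info),
    read_length = as.integer(read_length)), class = "AssignmentResult")
}

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# --- oracles ---------------------------------------------------------------

# All exact occurrences of `query` in the hybrid by direct window
# comparison (overlap-safe, both strands). Returns counts per strand and
# forward-strand 0-based positions per contig.
oracle_locate_counts <- function(hybrid, query) {
  k <- nchar(query)
  total <- 0L
  fwd_pos <- list()
  for (i in seq_len(nrow(hybrid$info))) {
    s <- hybrid$contigs[[i]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    wf <- substring(s, starts, starts + k - 1L)
    hits_f <- which(wf == query)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    wr <- substring(rc, starts, starts + k - 1L)
    hits_r <- which(wr == query)
    total <- total + length(hits_f) + length(hits_r)
    fwd_pos[[hybrid$info$contig[i]]] <- hits_f - 1L
  }
  list(total = total, fwd_pos = fwd_pos)
}

# Brute-force SNP-in-peak membership by double loop.
oracle_snps_in_peaks <- function(map, peaks) {
  rec <- map$records
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec)))
    for (j in seq_len(nrow(peaks$intervals))) {
      iv <- peaks$intervals[j]
      if (rec$chrom[i] == iv$chrom && rec$pos[i] >= iv$start &&
          rec$pos[i] < iv$end) keep[i] <- TRUE
    }
  rec[keep]
}

# Mean coverage over an explicit position list.
oracle_mean_at <- function(track, chrom, pos0) {
  vals <- mapply(function(ch, p) track$per_chromosome[[ch]][p + 1L],
                 chrom, pos0)
  mean(vals)
}

# Least squares via the normal equations, no lm().
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
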