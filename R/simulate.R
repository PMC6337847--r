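# Synthetic-experiment generator: colinear genome pairs differing by point
# substitutions, peaked binding profiles with condition-specific global
# abundance, cell mixtures at a configurable spike-in fraction, and
# error-free 100-bp single-end reads — plus the closed-form expectations
# that every estimator is tested against.

#' Simulation configuration
#'
#' Defaults state the regime being emulated: two colinear 100-kb
#' chromosomes at 0.7% divergence (the published strain pair's density),
#' a 80%:20% test:spike-in cell mixture, 100-bp single-end error-free
#' reads, 200,000 reads per sample, and a broadly bound target (many wide,
#' moderately enriched peaks). The spike-in's per-cell target abundance is
#' the unit (A_spike = 1); condition abundances are relative to it.
#'
#' @param seed Master seed; every sample draws from its own child stream
#'   derived from it, so adding conditions never perturbs existing samples.
#' @param n_chromosomes,chrom_length Genome shape (colinear pair).
#' @param divergence Per-base substitution probability in `[0, 0.1]`.
#' @param n_peaks,peak_width,enrichment_fold Binding profile: non-overlapping
#'   peaks of weight `enrichment_fold`, background weight 1.
#' @param background_fraction Optional target share of total profile weight
#'   contributed by background; `NULL` leaves weights unscaled.
#' @param spike_fraction Spike-in cell fraction `s` in `(0, 1)`.
#' @param abundance Named numeric: per-cell target level A per condition
#'   (relative to A_spike = 1).
#' @param read_length,n_reads,error_rate Read model; errors are substitution
#'   errors (the perfect-match aligner turns them into signal loss, never
#'   mis-assignment).
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 100000L,
                       divergence = 0.007, n_peaks = 24L, peak_width = 2000L,
                       enrichment_fold = 8, background_fraction = NULL,
                       spike_fraction = 0.2,
                       abundance = c(wildtype = 1),
                       read_length = 100L, n_reads = 200000L,
                       error_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              divergence = divergence, n_peaks = as.integer(n_peaks),
              peak_width = as.integer(peak_width),
              enrichment_fold = enrichment_fold,
              background_fraction = background_fraction,
              spike_fraction = spike_fraction, abundance = abundance,
              read_length = as.integer(read_length),
              n_reads = as.integer(n_reads), error_rate = error_rate)
  if (cfg$divergence < 0 || cfg$divergence > 0.1)
    stopf("divergence must be in [0, 0.1] (got %g)", cfg$divergence)
  if (cfg$spike_fraction <= 0 || cfg$spike_fraction >= 1)
    stopf("spike_fraction must be in (0, 1)")
  if (is.null(names(cfg$abundance)) || any(cfg$abundance <= 0))
    stopf("abundance must be a named vector of positive levels")
  if (cfg$enrichment_fold < 1) stopf("enrichment_fold must be >= 1")
  if (cfg$n_peaks * cfg$peak_width >=
      cfg$n_chromosomes * cfg$chrom_length)
    stopf("peaks do not fit in the genome")
  if (cfg$read_length > cfg$chrom_length)
    stopf("read_length exceeds chromosome length")
  structure(cfg, class = "SimConfig")
}

#' Simulate a colinear genome pair
#'
#' The test genome is i.i.d. uniform DNA; the spike-in genome copies it,
#' substituting each base independently with probability `divergence` to a
#' uniformly chosen different base. Every substitution is recorded in the
#' truth SNP map.
#'
#' @param config A [sim_config()] (or arguments to build one).
#' @return List with `test`, `spike` ([strain_genome()]s, strain ids `"T"`
#'   and `"S"`) and `snpmap` (truth [snp_map()]).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  bases <- c("A", "C", "G", "T")
  braw <- charToRaw("ACGT")
  with_seed(derive_seed(config$seed, "genome"), {
    test <- list(); spike <- list(); recs <- list()
    for (i in seq_len(config$n_chromosomes)) {
      ch <- sprintf("chr%02d", i)
      L <- config$chrom_length
      code <- sample.int(4L, L, replace = TRUE)
      sub_at <- if (config$divergence > 0)
        which(stats::runif(L) < config$divergence) else integer()
      scode <- code
      if (length(sub_at)) {
        off <- sample.int(3L, length(sub_at), replace = TRUE)
        scode[sub_at] <- (code[sub_at] + off - 1L) %% 4L + 1L
        recs[[i]] <- data.table::data.table(
          chrom = ch, pos = sub_at - 1L,
          allele_test = bases[code[sub_at]],
          allele_spike = bases[scode[sub_at]])
      }
      test[[ch]] <- rawToChar(braw[code])
      spike[[ch]] <- rawToChar(braw[scode])
    }
    rec <- data.table::rbindlist(recs)
    if (!nrow(rec))
      rec <- data.table::data.table(chrom = character(), pos = integer(),
                                    allele_test = character(),
                                    allele_spike = character())
    list(test = strain_genome("T", unlist(test)),
         spike = strain_genome("S", unlist(spike)),
         snpmap = snp_map(rec,
                          genome_length = config$n_chromosomes * config$chrom_length,
                          chroms = names(test)))
  })
}

#' Simulate a peaked binding profile
#'
#' Places `n_peaks` non-overlapping peaks uniformly at random across the
#' genome (chromosome chosen proportional to length). Profile weight is
#' `enrichment_fold` inside peaks and 1 outside; when
#' `background_fraction` is given, background weights are rescaled so the
#' background contributes that share of the total weight W.
#'
#' @param genome A [strain_genome()].
#' @param n_peaks,peak_width,enrichment_fold,background_fraction See
#'   [sim_config()].
#' @param seed Integer seed.
#' @return List with `profile` (a `BindingProfile`: per-chromosome weight
#'   vectors plus total weight `W`) and `peaks` (a [peak_set()]).
#' @export
simulate_binding_profile <- function(genome, n_peaks, peak_width,
                                     enrichment_fold,
                                     background_fraction = NULL, seed = 1L) {
  stopifnot(inherits(genome, "StrainGenome"))
  lens <- nchar(genome$chromosomes)
  if (n_peaks * peak_width >= sum(lens))
    stopf("peaks do not fit in the genome")
  placed <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  if (n_peaks > 0L) with_seed(seed, {
    tries <- 0L
    while (nrow(placed) < n_peaks) {
      if ((tries <- tries + 1L) > 1000L * n_peaks)
        stopf("could not place %d non-overlapping peaks after %d tries",
              n_peaks, tries)
      ci <- sample.int(length(lens), 1L, prob = lens)
      ch <- names(lens)[ci]
      if (lens[ci] < peak_width) next
      s <- sample.int(lens[ci] - peak_width + 1L, 1L) - 1L
      e <- s + peak_width
      if (nrow(placed[chrom == ch & start < e & end > s])) next
      placed <- rbind(placed,
                      data.table::data.table(chrom = ch, start = s, end = e))
    }
  })
  weights <- lapply(lens, function(L) rep(1, L))
  for (i in seq_len(nrow(placed)))
    weights[[placed$chrom[i]]][(placed$start[i] + 1L):placed$end[i]] <-
      enrichment_fold
  if (!is.null(background_fraction)) {
    n_bg <- sum(lens) - n_peaks * peak_width
    n_pk <- n_peaks * peak_width
    if (n_pk > 0L && n_bg > 0L) {
      b <- background_fraction / (1 - background_fraction) *
        enrichment_fold * n_pk / n_bg
      weights <- lapply(weights, function(w) ifelse(w == 1, b, w))
    }
  }
  profile <- structure(list(per_chromosome = weights,
                            W = sum(vapply(weights, sum, numeric(1)))),
                       class = "BindingProfile")
  peaks <- if (nrow(placed)) peak_set(placed$chrom, placed$start, placed$end)
           else peak_set(character(), integer(), integer())
  list(profile = profile, peaks = peaks)
}

#' Build the full simulated world for a configuration
#'
#' Deterministically derives the genome pair, truth SNP map, and the (shared,
#' colinear) binding profile from `config$seed`. Callers running several
#' samples should build the world once and pass it to [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return A `SimWorld` list: `test`, `spike`, `snpmap`, `profile`,
#'   `peaks`, `config`.
#' @export
sim_world <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  gp <- simulate_genome_pair(config)
  bp <- simulate_binding_profile(gp$test, config$n_peaks, config$peak_width,
                                 config$enrichment_fold,
                                 config$background_fraction,
                                 seed = derive_seed(config$seed, "profile"))
  structure(list(test = gp$test, spike = gp$spike, snpmap = gp$snpmap,
                 profile = bp$profile, peaks = bp$peaks, config = config),
            class = "SimWorld")
}

# Per-start-position sampling weights for one genome: profile weight at the
# read start, restricted to starts where the read fits. Binding profiles are
# shared between the colinear genomes, so the same weights serve both.
start_weights <- function(world, uniform = FALSE) {
  k <- world$config$read_length
  lapply(world$profile$per_chromosome, function(w) {
    n <- length(w) - k + 1L
    if (uniform) rep(1, n) else w[seq_len(n)]
  })
}

#' Simulate one sequenced sample
#'
#' Input sample: each read's genome of origin is drawn with
#' `P(spike) = s * L_spike / (s * L_spike + (1 - s) * L_test)` and its
#' position uniformly. ChIP sample: `P(spike) = s * A_spike * W_spike /
#' (s * A_spike * W_spike + (1 - s) * A_cond * W_test)` and position
#' proportional to profile weight at the read start. Reads are exact
#' substrings of their genome (strand uniform, reverse-complemented on
#' `-`), with optional substitution errors. L and W are evaluated over
#' valid read start positions so Monte-Carlo estimates converge to
#' [expected_values()] exactly.
#'
#' @param config A [sim_config()].
#' @param condition_id Name of an entry of `config$abundance`.
#' @param sample_role `"ChIP"` or `"Input"`.
#' @param world Optional prebuilt [sim_world()] (avoids regeneration).
#' @return List with `reads` (a [read_set()] carrying `truth_origin`) and
#'   `truth` (a `SimTruth`: `snpmap`, `peaks`, `s`, `abundance`,
#'   `expected`).
#' @export
simulate_reads <- function(config, condition_id, sample_role = c("ChIP", "Input"),
                           world = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  sample_role <- match.arg(sample_role)
  if (!condition_id %in% names(config$abundance))
    stopf("condition '%s' has no abundance entry", condition_id)
  world <- world %||% sim_world(config)
  k <- config$read_length
  s <- config$spike_fraction
  uniform <- sample_role == "Input"
  w <- start_weights(world, uniform = uniform)
  w_tot <- vapply(w, sum, numeric(1))
  W <- sum(w_tot)            # identical for both colinear genomes
  A_cond <- unname(config$abundance[[condition_id]])
  p_spike <- if (uniform) s * W / (s * W + (1 - s) * W)
             else s * 1 * W / (s * 1 * W + (1 - s) * A_cond * W)
  n <- config$n_reads
  with_seed(derive_seed(config$seed, "reads", condition_id, sample_role), {
    n_spike <- stats::rbinom(1L, n, p_spike)
    n_test <- n - n_spike
    flat_w <- unlist(w, use.names = FALSE)
    draw <- function(n_draw, genome) {
      if (n_draw == 0L) return(NULL)
      gi <- sample.int(length(flat_w), n_draw, replace = TRUE, prob = flat_w)
      # map flat index back to (chrom, start0)
      sizes <- vapply(w, length, integer(1))
      ends <- cumsum(sizes)
      ci <- findInterval(gi, c(0, ends), left.open = TRUE)
      start0 <- gi - c(0L, ends)[ci] - 1L
      chrom <- names(w)[ci]
      seqs <- substring(genome$chromosomes[chrom], start0 + 1L, start0 + k)
      minus <- sample(c(TRUE, FALSE), n_draw, replace = TRUE)
      if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
      data.table::data.table(chrom = chrom, start0 = start0,
                             strand = ifelse(minus, "-", "+"), seq = seqs)
    }
    rt <- draw(n_test, world$test)
    rs <- draw(n_spike, world$spike)
    dt <- data.table::rbindlist(list(rt, rs))
    origin <- rep(c("test", "spike"), c(n_test, n_spike))
    # shuffle so read order carries no origin information
    ord <- sample.int(n)
    dt <- dt[ord]; origin <- origin[ord]
    if (config$error_rate > 0) {
      allseq <- charToRaw(paste0(dt$seq, collapse = ""))
      err_at <- which(stats::runif(length(allseq)) < config$error_rate)
      if (length(err_at)) {
        bmap <- charToRaw("ACGT")
        cur <- match(as.integer(allseq[err_at]), as.integer(bmap))
        off <- sample.int(3L, length(err_at), replace = TRUE)
        allseq[err_at] <- bmap[(cur + off - 1L) %% 4L + 1L]
        all_str <- rawToChar(allseq)
        starts <- seq(1L, by = k, length.out = n)
        dt$seq <- substring(all_str, starts, starts + k - 1L)
      }
    }
    reads <- read_set(sprintf("%s_%s_%07d", condition_id, sample_role,
                              seq_len(n)),
                      dt$seq, truth_origin = origin)
    truth <- structure(list(snpmap = world$snpmap, peaks = world$peaks,
                            s = s, abundance = config$abundance,
                            expected = expected_values(config, condition_id,
                                                       world)),
                       class = "SimTruth")
    list(reads = reads, truth = truth)
  })
}

#' Closed-form expected quotients and normalization factor
#'
#' `Q_input = s * L_spike / ((1 - s) * L_test)`;
#' `Q_chip = s * A_spike * W_spike / ((1 - s) * A_cond * W_test)`;
#' `Nf = Q_input / Q_chip = (A_cond * W_test * L_spike) /
#' (A_spike * W_spike * L_test)`, which reduces to `A_cond / A_spike` for
#' matched lengths and profiles (the simulator's colinear world). L and W
#' are evaluated over valid read start positions, matching the sampler.
#'
#' @param config A [sim_config()].
#' @param condition_id Condition name.
#' @param world Optional prebuilt [sim_world()].
#' @return List with `Q_input`, `Q_chip`, `Nf`.
#' @export
expected_values <- function(config, condition_id, world = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (!condition_id %in% names(config$abundance))
    stopf("condition '%s' has no abundance entry", condition_id)
  world <- world %||% sim_world(config)
  s <- config$spike_fraction
  A_cond <- unname(config$abundance[[condition_id]])
  L <- sum(vapply(start_weights(world, uniform = TRUE), sum, numeric(1)))
  W <- sum(vapply(start_weights(world, uniform = FALSE), sum, numeric(1)))
  q_in <- s * L / ((1 - s) * L)
  q_ch <- s * 1 * W / ((1 - s) * A_cond * W)
  list(Q_input = q_in, Q_chip = q_ch, Nf = q_in / q_ch)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits both genomes and the hybrid as FASTA, one FASTQ per
#' condition x role, a truth JSON (SNP count, peaks, s, abundances,
#' expected values), and a manifest holding the full configuration.
#' Regenerating from the manifest's config is byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  world <- sim_world(config)
  write_genome_fasta(world$test, file.path(out_dir, "test.fa"))
  write_genome_fasta(world$spike, file.path(out_dir, "spike.fa"))
  hybrid <- build_hybrid_reference(world$test, world$spike)
  write_genome_fasta(hybrid, file.path(out_dir, "hybrid.fa"))
  write_snp_map(world$snpmap, file.path(out_dir, "snps.tsv"))
  write_bed(world$peaks, file.path(out_dir, "peaks.bed"))
  files <- character()
  truths <- list()
  for (cid in names(config$abundance)) for (role in c("ChIP", "Input")) {
    sim <- simulate_reads(config, cid, role, world)
    fn <- sprintf("%s_%s.fastq", cid, tolower(role))
    write_reads_fastq(sim$reads, file.path(out_dir, fn))
    files <- c(files, fn)
    truths[[cid]] <- sim$truth$expected
  }
  truth <- list(n_snps = nrow(world$snpmap$records),
                n_peaks = nrow(world$peaks$intervals),
                spike_fraction = config$spike_fraction,
                abundance = as.list(config$abundance),
                expected = truths)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- unclass(config)
  cfg_out$abundance <- as.list(cfg_out$abundance)  # keep names through JSON
  manifest <- list(config = cfg_out, files = files,
                   package_version = as.character(utils::packageVersion("snipchip")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
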