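# Coverage pileups, mean pileup scores, depth/spike-in scaling, and the
# interval formats (bedGraph tracks, BED peaks).

#' Construct a pileup track
#'
#' Per-base read coverage for one genome. Values are non-negative integers
#' before scaling and reals after.
#'
#' @param genome_id `"test"` or `"spike"`.
#' @param per_chromosome Named list of numeric coverage vectors, one per
#'   chromosome, each of the chromosome's length.
#' @param n_reads_used Number of reads that contributed.
#' @return A `PileupTrack`.
#' @export
pileup_track <- function(genome_id, per_chromosome, n_reads_used = NA_integer_) {
  genome_id <- match.arg(genome_id, c("test", "spike"))
  if (!length(per_chromosome) || is.null(names(per_chromosome)))
    stopf("per_chromosome must be a named list of coverage vectors")
  structure(list(genome_id = genome_id, per_chromosome = per_chromosome,
                 n_reads_used = n_reads_used),
            class = "PileupTrack")
}

#' @export
print.PileupTrack <- function(x, ...) {
  tot <- sum(vapply(x$per_chromosome, sum, numeric(1)))
  len <- sum(vapply(x$per_chromosome, length, numeric(1)))
  cat(sprintf("PileupTrack [%s]: %d chromosome(s), %s bp, mean %.4g\n",
              x$genome_id, length(x$per_chromosome),
              format(len, big.mark = ","), tot / len))
  invisible(x)
}

track_length <- function(track) sum(vapply(track$per_chromosome, length,
                                           numeric(1)))
track_mass <- function(track) sum(vapply(track$per_chromosome, sum,
                                         numeric(1)))

#' Pileup coverage from an assignment
#'
#' Each read assigned to `genome_id` adds +1 over `[start, start +
#' read_length)` of its chromosome; ambiguous and unmapped reads contribute
#' nothing. Reads are piled at their full length without fragment-size
#' extension: a constant extension factor cancels in the quotient Q, which
#' is what these tracks feed.
#'
#' @param result An [assign_reads()] result.
#' @param read_length Read length in bp; defaults to the assignment's.
#' @param genome_id `"test"` or `"spike"`.
#' @return A [pileup_track()].
#' @export
pileup_from_assignment <- function(result, read_length = NULL,
                                   genome_id = c("test", "spike")) {
  stopifnot(inherits(result, "AssignmentResult"))
  genome_id <- match.arg(genome_id)
  read_length <- as.integer(read_length %||% result$read_length)
  if (is.na(read_length)) stopf("read_length required for mixed-length reads")
  info <- result$info[origin == genome_id]
  per <- result$per_read[call == genome_id]
  cov <- vector("list", nrow(info))
  names(cov) <- info$chrom
  for (i in seq_len(nrow(info))) {
    L <- info$length[i]
    s0 <- per$start0[per$contig == info$contig[i]]
    if (length(s0) && max(s0) + read_length > L)
      stopf("placement beyond chromosome '%s' end", info$chrom[i])
    d <- tabulate(s0 + 1L, nbins = L + 1L) -
      tabulate(s0 + read_length + 1L, nbins = L + 1L)
    cov[[i]] <- cumsum(d)[seq_len(L)]
  }
  pileup_track(genome_id, cov, n_reads_used = nrow(per))
}

#' Mean pileup score over a position subset
#'
#' The three pileup-based estimator variants use the arithmetic mean
#' coverage over (1) every base of the genome, (2) SNP positions only, or
#' (3) SNP positions inside signal peaks.
#'
#' @param track A [pileup_track()].
#' @param mode `"all"`, `"snp"`, or `"snp_peaks"`.
#' @param snpmap [snp_map()]; required for the restricted modes.
#' @param peaks [peak_set()] on test-genome coordinates; required for
#'   `"snp_peaks"`. Colinearity lets the same coordinates index the spike
#'   genome.
#' @return Scalar mean coverage.
#' @export
mean_pileup <- function(track, mode = c("all", "snp", "snp_peaks"),
                        snpmap = NULL, peaks = NULL) {
  stopifnot(inherits(track, "PileupTrack"))
  mode <- match.arg(mode)
  if (mode == "all") return(track_mass(track) / track_length(track))
  if (is.null(snpmap)) stopf("mode '%s' requires a SnpMap", mode)
  if (mode == "snp_peaks") {
    if (is.null(peaks)) stopf("mode 'snp_peaks' requires a PeakSet")
    snpmap <- snps_in_intervals(snpmap, peaks)
  }
  rec <- snpmap$records[chrom %in% names(track$per_chromosome)]
  if (nrow(rec) == 0L)
    stopf("mean_pileup: empty position subset for mode '%s'", mode)
  vals <- rec[, .(v = track$per_chromosome[[.BY$chrom]][pos + 1L]),
              by = "chrom"]$v
  mean(vals)
}

#' Mean coverage per chromosome
#'
#' The per-chromosome analogue of the genome-wide mean; on spike-in-scaled
#' tracks this is the statistic used to compare average signal between
#' individual chromosomes.
#'
#' @param track A [pileup_track()].
#' @return Named numeric vector in genome chromosome order.
#' @export
per_chromosome_mean <- function(track) {
  stopifnot(inherits(track, "PileupTrack"))
  vapply(track$per_chromosome, mean, numeric(1))
}

#' Scale a track to signal per million reads
#'
#' Depth normalization ("fragment pileup per million reads"): every value is
#' multiplied by `1e6 / total_assigned_reads`.
#'
#' @param track A [pileup_track()].
#' @param total_assigned_reads Positive read count (defaults to the track's
#'   own `n_reads_used`).
#' @return The scaled [pileup_track()].
#' @export
spmr_scale <- function(track, total_assigned_reads = NULL) {
  stopifnot(inherits(track, "PileupTrack"))
  n <- total_assigned_reads %||% track$n_reads_used
  if (is.na(n) || n <= 0) stopf("spmr_scale: total_assigned_reads must be > 0")
  track$per_chromosome <- lapply(track$per_chromosome, `*`, 1e6 / n)
  track
}

#' Apply a spike-in normalization factor to a track
#'
#' Pointwise multiplication by Nf; commutes with [spmr_scale()].
#'
#' @param track A [pileup_track()].
#' @param nf A `NormFactor` or a positive scalar.
#' @return The scaled [pileup_track()].
#' @export
apply_norm_factor <- function(track, nf) {
  stopifnot(inherits(track, "PileupTrack"))
  v <- if (inherits(nf, "NormFactor")) nf$value else nf
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    stopf("normalization factor must be a positive scalar")
  track$per_chromosome <- lapply(track$per_chromosome, `*`, v)
  track
}

#' Construct a peak set
#'
#' 0-based half-open intervals, sorted within chromosomes; overlapping or
#' bookended intervals are merged on construction (merged intervals get
#' fresh names and score `NA`).
#'
#' @param chrom,start,end Interval columns (start < end).
#' @param name,score Optional per-interval annotations.
#' @return A `PeakSet` with element `intervals` (a `data.table`).
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL) {
  n <- length(chrom)
  iv <- data.table::data.table(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end),
    name = if (is.null(name)) paste0("peak_", seq_len(n)) else as.character(name),
    score = if (is.null(score)) NA_real_ else as.numeric(score))
  if (nrow(iv) && any(iv$start >= iv$end)) stopf("peak with start >= end")
  if (nrow(iv)) {
    gr <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start + 1L, iv$end))
    red <- GenomicRanges::reduce(gr)
    if (length(red) < nrow(iv)) {
      ov <- data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(red)),
        start = GenomicRanges::start(red) - 1L,
        end = GenomicRanges::end(red))
      ov[, `:=`(name = paste0("peak_", .I), score = NA_real_)]
      iv <- ov
    }
  }
  data.table::setorder(iv, chrom, start)
  structure(list(intervals = iv), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d interval(s), %s bp total\n", nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start),
                     big.mark = ",")))
  invisible(x)
}

#' Naive threshold peak caller
#'
#' Fixture-grade caller for synthetic data: the input track is scaled to the
#' ChIP track's background level (ratio of the two tracks' median coverage;
#' total-mass ratio as fallback when a median is zero), then maximal runs
#' where ChIP/input >= `fold` and of length >= `min_width` become peaks.
#' Median scaling keeps the enrichment threshold meaningful for broadly
#' bound targets, where peak reads are a large share of total mass. It
#' replaces no production peak caller; real-data peaks should come from a
#' dedicated tool via [read_bed()].
#'
#' @param chip,input [pileup_track()]s on the same genome.
#' @param fold Enrichment threshold (>= the scaled input).
#' @param min_width Minimum run length in bp (applied after gap merging).
#' @param max_gap Merge qualifying runs separated by at most this many bp.
#'   SNP-assigned coverage has zero-coverage holes wherever consecutive
#'   SNPs are farther apart than the read length, so recovering broad
#'   peaks from classified reads needs a few hundred bp of bridging; 0
#'   keeps the strict maximal-run semantics.
#' @return A [peak_set()].
#' @export
call_peaks_naive <- function(chip, input, fold = 4, min_width = 100L,
                             max_gap = 0L) {
  stopifnot(inherits(chip, "PileupTrack"), inherits(input, "PileupTrack"))
  if (!identical(names(chip$per_chromosome), names(input$per_chromosome)))
    stopf("chip and input tracks cover different chromosomes")
  im <- track_mass(input)
  if (im <= 0) stopf("call_peaks_naive: flat zero input track")
  med_chip <- stats::median(unlist(chip$per_chromosome, use.names = FALSE))
  med_input <- stats::median(unlist(input$per_chromosome, use.names = FALSE))
  f <- if (med_chip > 0 && med_input > 0) med_chip / med_input
       else track_mass(chip) / im
  out <- list()
  for (ch in names(chip$per_chromosome)) {
    cc <- chip$per_chromosome[[ch]]
    ic <- input$per_chromosome[[ch]] * f
    enr <- ifelse(ic > 0, cc / ic, ifelse(cc > 0, Inf, 0))
    r <- rle(enr >= fold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.table::data.table(start = starts[r$values] - 1L,
                                   end = ends[r$values])
    if (nrow(runs) > 1L && max_gap > 0L) {
      grp <- cumsum(c(0L, (runs$start[-1L] - runs$end[-nrow(runs)]) > max_gap))
      runs <- runs[, .(start = min(start), end = max(end)), by = grp][, !"grp"]
    }
    runs <- runs[end - start >= min_width]
    if (nrow(runs))
      out[[ch]] <- data.table::data.table(chrom = ch, start = runs$start,
                                          end = runs$end)
  }
  iv <- data.table::rbindlist(out)
  if (!nrow(iv)) return(peak_set(character(), integer(), integer()))
  peak_set(iv$chrom, iv$start, iv$end)
}

#' Write a pileup track as bedGraph
#'
#' Runs of equal value are merged; values are printed with enough digits to
#' round-trip doubles exactly.
#'
#' @param track A [pileup_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "PileupTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$per_chromosome)) {
    r <- rle(track$per_chromosome[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a pileup track
#'
#' @param path bedGraph path.
#' @param genome_id `"test"` or `"spike"`.
#' @param chrom_lengths Optional named lengths; defaults to the maximum end
#'   seen per chromosome.
#' @return A [pileup_track()].
#' @export
read_bedgraph <- function(path, genome_id = "test", chrom_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) != 4L)
    stopf("malformed bedGraph '%s': expected 4 tab-separated columns", path)
  dt <- data.table::data.table(chrom = parts[[1]],
                               start = suppressWarnings(as.integer(parts[[2]])),
                               end = suppressWarnings(as.integer(parts[[3]])),
                               value = suppressWarnings(as.numeric(parts[[4]])))
  bad <- which(is.na(dt$start) | is.na(dt$end) | is.na(dt$value))
  if (length(bad)) stopf("malformed bedGraph '%s' at line %d", path, bad[1])
  chroms <- unique(dt$chrom)
  cov <- lapply(chroms, function(ch) {
    d <- dt[chrom == ch]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(d$end)
    v <- numeric(L)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    v
  })
  names(cov) <- chroms
  pileup_track(genome_id, cov)
}

#' Read peaks from a BED file
#'
#' Standard 0-based half-open BED; overlapping intervals are merged on load.
#'
#' @param path BED path.
#' @return A [peak_set()].
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stopf("malformed BED '%s': %s", path, conditionMessage(e)))
  if (length(gr) == 0L) return(peak_set(character(), integer(), integer()))
  nm <- if (!is.null(gr$name)) gr$name else NULL
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else NULL
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           name = nm, score = sc)
}

#' Write peaks to a BED file
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  iv <- peaks$intervals
  sc <- ifelse(is.na(iv$score), 0, iv$score)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g", iv$chrom, iv$start, iv$end,
                     iv$name, sc), path)
  invisible(path)
}
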