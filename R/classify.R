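# Read assignment under the perfect-match, unique-placement rule: a read is
# kept only if its sequence occurs at exactly one location (either strand)
# in the hybrid reference, in which case the contig of that location decides
# its genome of origin.

#' Construct a read set
#'
#' Single-end reads; qualities are ignored throughout (alignment is exact).
#'
#' @param read_id Character vector of unique read identifiers.
#' @param seq Character vector of read sequences over `{A,C,G,T,N}`,
#'   minimum length 20.
#' @param truth_origin Optional `{test, spike}` labels carried by simulated
#'   reads; never consulted by classification.
#' @return A `ReadSet` (a `data.table` with columns `read_id`, `seq`,
#'   `truth_origin`).
#' @export
read_set <- function(read_id, seq, truth_origin = NA_character_) {
  if (length(read_id) != length(seq))
    stopf("read_id and seq lengths differ")
  if (anyDuplicated(read_id)) stopf("duplicate read_ids")
  seq <- check_dna(seq, "read")
  if (any(nchar(seq) < 20L))
    stopf("reads shorter than 20 bases are not supported")
  rs <- data.table::data.table(read_id = as.character(read_id), seq = seq,
                               truth_origin = truth_origin)
  data.table::setattr(rs, "class", c("ReadSet", class(rs)))
  rs[]
}

#' Read single-end reads from FASTQ
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return A [read_set()].
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  read_set(sub("\\s.*$", "", names(x)), as.character(x))
}

#' Write a read set to FASTQ
#'
#' Qualities are written as constant 'I' (Phred 40): exact matching never
#' consults them.
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(vapply(nchar(reads$seq),
                                        function(n) strrep("I", n),
                                        character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Build an exact-match index over a hybrid reference
#'
#' Enumerates every length-k window of every contig on both strands and
#' stores them in a hash-joinable table, so that all exact occurrences of a
#' k-mer query can be located at once. This stands in for an external
#' aligner run at end-to-end, zero-mismatch settings. Windows for other
#' query lengths are built lazily and cached.
#'
#' @param hybrid A [build_hybrid_reference()] result.
#' @param read_length_hint Window length to pre-build (default 100, the
#'   recommended minimum read length for this protocol).
#' @return An `ExactIndex`.
#' @export
build_exact_index <- function(hybrid, read_length_hint = 100L) {
  stopifnot(inherits(hybrid, "HybridReference"))
  if (sum(hybrid$info$length) == 0L) stopf("empty hybrid reference")
  idx <- structure(
    list(contigs = hybrid$contigs,
         rc = revcomp(hybrid$contigs),
         info = data.table::copy(hybrid$info),
         cache = new.env(parent = emptyenv())),
    class = "ExactIndex")
  if (!is.null(read_length_hint)) index_tables(idx, as.integer(read_length_hint))
  idx
}

# Window tables for query length k: `full` holds every placement in
# deterministic order (contig order, then position, then + before -);
# `agg` maps each distinct window sequence to its placement count and, when
# unique, its single placement.
index_tables <- function(index, k) {
  key <- as.character(k)
  cached <- get0(key, envir = index$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  info <- index$info
  parts <- vector("list", 2L * nrow(info))
  for (i in seq_len(nrow(info))) {
    L <- info$length[i]
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    fwd <- substring(index$contigs[[i]], starts, starts + k - 1L)
    parts[[2L * i - 1L]] <- data.table::data.table(
      seq = fwd, ci = i, start0 = starts - 1L, srank = 0L)
    rev <- substring(index$rc[[i]], starts, starts + k - 1L)
    parts[[2L * i]] <- data.table::data.table(
      seq = rev, ci = i, start0 = L - starts - k + 1L, srank = 1L)
  }
  full <- data.table::rbindlist(parts)
  if (!nrow(full))
    stopf("no contig is long enough for %d-mer queries", k)
  data.table::setorder(full, ci, start0, srank)
  ci <- start0 <- srank <- NULL  # NSE guard
  agg <- full[, .(n = .N, ci = ci[1L], start0 = start0[1L], srank = srank[1L]),
              by = "seq"]
  data.table::setkey(agg, seq)
  tabs <- list(full = full, agg = agg)
  assign(key, tabs, envir = index$cache)
  tabs
}

#' Locate all exact occurrences of a query
#'
#' @param index An [build_exact_index()] result.
#' @param query A single DNA string.
#' @return A `data.table` with columns `contig`, `start0` (0-based),
#'   `strand`, ordered by contig, position, then `+` before `-`. Zero rows
#'   when the query occurs nowhere.
#' @export
locate <- function(index, query) {
  stopifnot(inherits(index, "ExactIndex"))
  query <- toupper(query)
  if (grepl("N", query, fixed = TRUE) ||
      nchar(query) > max(index$info$length))
    return(data.table::data.table(contig = character(), start0 = integer(),
                                  strand = character()))
  tabs <- index_tables(index, nchar(query))
  hits <- tabs$full[seq == query]
  data.table::data.table(contig = index$info$contig[hits$ci],
                         start0 = hits$start0,
                         strand = c("+", "-")[hits$srank + 1L])
}

#' Assign reads to their genome of origin
#'
#' Implements the perfect-match rule: a read placed at exactly one hybrid
#' location is assigned to that contig's genome; reads matching nowhere
#' (including any read containing an N) are `unmapped`; reads matching more
#' than one location — typically because they span no SNP and therefore
#' occur in both genomes — are `ambiguous` and discarded. A palindromic
#' read matching one locus on both strands counts as two placements.
#'
#' @param reads A [read_set()].
#' @param index An [build_exact_index()] over the hybrid.
#' @param origin_of Optional named character vector contig -> `{test,
#'   spike}`; defaults to the index's own contig table.
#' @return An `AssignmentResult`: list with `per_read` (`data.table`:
#'   `read_id`, `call`, `contig`, `start0`, `strand`), counts `C_endo`,
#'   `C_spike`, `n_ambiguous`, `n_unmapped`, the contig `info` table, and
#'   `read_length` (NA when mixed).
#' @export
assign_reads <- function(reads, index, origin_of = NULL) {
  stopifnot(inherits(index, "ExactIndex"))
  if (NROW(reads) == 0L) stopf("assign_reads: empty read set")
  if (is.null(origin_of))
    origin_of <- stats::setNames(index$info$origin, index$info$contig)
  per <- data.table::data.table(
    read_id = reads$read_id,
    call = "unmapped",
    contig = NA_character_, start0 = NA_integer_, strand = NA_character_)
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  lens <- nchar(reads$seq)
  for (k in unique(lens[!has_n])) {
    sel <- which(lens == k & !has_n)
    tabs <- index_tables(index, k)
    m <- tabs$agg[data.table::data.table(seq = reads$seq[sel]), on = "seq"]
    one <- which(!is.na(m$n) & m$n == 1L)
    multi <- which(!is.na(m$n) & m$n > 1L)
    if (length(one)) {
      ri <- sel[one]
      ctg <- index$info$contig[m$ci[one]]
      data.table::set(per, ri, "call", unname(origin_of[ctg]))
      data.table::set(per, ri, "contig", ctg)
      data.table::set(per, ri, "start0", m$start0[one])
      data.table::set(per, ri, "strand", c("+", "-")[m$srank[one] + 1L])
    }
    if (length(multi)) data.table::set(per, sel[multi], "call", "ambiguous")
  }
  res <- structure(list(
    per_read = per,
    C_endo = sum(per$call == "test"),
    C_spike = sum(per$call == "spike"),
    n_ambiguous = sum(per$call == "ambiguous"),
    n_unmapped = sum(per$call == "unmapped"),
    info = data.table::copy(index$info),
    read_length = if (length(unique(lens)) == 1L) lens[1L] else NA_integer_
  ), class = "AssignmentResult")
  stopifnot(res$C_endo + res$C_spike + res$n_ambiguous + res$n_unmapped ==
              nrow(per))
  res
}

#' @export
print.AssignmentResult <- function(x, ...) {
  n <- nrow(x$per_read)
  cat(sprintf(paste0("AssignmentResult: %s reads | test %s (%.1f%%), ",
                     "spike %s (%.1f%%), ambiguous %s, unmapped %s\n"),
              format(n, big.mark = ","), format(x$C_endo, big.mark = ","),
              100 * x$C_endo / n, format(x$C_spike, big.mark = ","),
              100 * x$C_spike / n, format(x$n_ambiguous, big.mark = ","),
              format(x$n_unmapped, big.mark = ",")))
  invisible(x)
}

#' Per-genome read counts from an external per-contig summary table
#'
#' Ingests the per-contig mapped-read summary an external alignment toolkit
#' emits (contig, contig length, mapped, unmapped — the `samtools idxstats`
#' layout, with or without a header row) and sums mapped reads by genome of
#' origin. This is the entry point for the real-data workflow, where
#' alignment to the hybrid reference was done outside this package.
#'
#' @param path TSV path.
#' @param origin_of Named character vector contig -> `{test, spike}`.
#' @return List with `C_endo` and `C_spike`.
#' @export
counts_from_contig_table <- function(path, origin_of) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 3L) stopf("contig table needs >= 3 columns (contig, length, mapped)")
  data.table::setnames(dt, 1:3, c("contig", "length", "mapped"))
  dt[, c("contig", "mapped") := .(as.character(contig), as.numeric(mapped))]
  known <- dt$contig %in% names(origin_of)
  if (!any(known))
    stopf("no recognizable contigs in '%s'", path)
  if (any(!known))
    message(sprintf("counts_from_contig_table: ignored %d unknown contig(s): %s",
                    sum(!known),
                    paste(utils::head(dt$contig[!known], 3), collapse = ", ")))
  org <- origin_of[dt$contig[known]]
  C_endo <- sum(dt$mapped[known][org == "test"])
  C_spike <- sum(dt$mapped[known][org == "spike"])
  if (C_spike == 0)
    warnf("no spike-in reads in contig table; Q will be 0")
  list(C_endo = C_endo, C_spike = C_spike)
}

#' Write an assignment's per-contig counts as a summary table
#'
#' Emits the same four-column layout as `samtools idxstats` so that
#' in-package assignments round-trip through [counts_from_contig_table()].
#'
#' @param result An [assign_reads()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(result, path) {
  stopifnot(inherits(result, "AssignmentResult"))
  tab <- result$per_read[!is.na(contig), .N, by = "contig"]
  info <- data.table::copy(result$info)
  info[tab, n_mapped := i.N, on = "contig"]
  info[is.na(n_mapped), n_mapped := 0L]
  out <- info[, .(contig, length, n_mapped, n_unmapped = 0L)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Fraction of read-length windows that are assignable
#'
#' For every start position in both genomes (forward-strand windows), a
#' window is assignable when it contains at least one SNP and its sequence
#' occurs exactly once in the hybrid (either strand). This is the
#' theoretical ceiling on the fraction of reads kept by classification; at
#' the published regime (~0.7% divergence, 100-bp reads) the SNP-containing
#' fraction is bounded by 1 - (1 - d)^100, roughly one half.
#'
#' @param hybrid A [build_hybrid_reference()] result.
#' @param snpmap The pair's [snp_map()].
#' @param read_length Window length (>= 1).
#' @param max_enumerate Enumerate fully when the total number of windows is
#'   at most this; otherwise sample `n_sample` windows with a fixed seed.
#' @param n_sample,seed Sampling controls for large genomes.
#' @return Assignable fraction in `[0, 1]`.
#' @export
assignable_fraction <- function(hybrid, snpmap, read_length,
                                max_enumerate = 2e6, n_sample = 2e5,
                                seed = 1L) {
  stopifnot(inherits(hybrid, "HybridReference"), inherits(snpmap, "SnpMap"))
  read_length <- as.integer(read_length)
  if (read_length < 1L) stopf("read_length must be >= 1")
  if (read_length > min(hybrid$info$length))
    stopf("read_length %d exceeds the shortest chromosome (%d bp)",
          read_length, min(hybrid$info$length))
  index <- build_exact_index(hybrid, read_length)
  tabs <- index_tables(index, read_length)
  fwd <- tabs$full[srank == 0L]
  # SNP-overlap flag per forward window: start s (0-based) covers a SNP at
  # pos iff s in [pos - k + 1, pos]
  snp_flag <- logical(nrow(fwd))
  rec <- snpmap$records
  for (i in seq_len(nrow(index$info))) {
    rows <- which(fwd$ci == i)
    if (!length(rows)) next
    p <- rec$pos[rec$chrom == index$info$chrom[i]]
    if (!length(p)) next
    ir <- IRanges::reduce(IRanges::IRanges(pmax(p - read_length + 1L, 0L) + 1L,
                                           p + 1L))
    ol <- IRanges::findOverlaps(IRanges::IRanges(fwd$start0[rows] + 1L,
                                                 width = 1L), ir)
    snp_flag[rows[S4Vectors::queryHits(ol)]] <- TRUE
  }
  if (nrow(fwd) > max_enumerate) {
    pick <- with_seed(derive_seed(seed, "assignable"),
                      sample.int(nrow(fwd), n_sample))
  } else pick <- seq_len(nrow(fwd))
  m <- tabs$agg[data.table::data.table(seq = fwd$seq[pick]), on = "seq"]
  mean(snp_flag[pick] & m$n == 1L)
}
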