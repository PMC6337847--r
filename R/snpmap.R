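# Strain genomes, the concatenated hybrid reference, and the SNP map that
# distinguishes the two genomes.

#' Construct a strain genome
#'
#' A `StrainGenome` is an ordered set of named chromosome sequences belonging
#' to one strain (e.g. the test strain under study or the strain providing
#' the spike-in material).
#'
#' @param strain_id Short strain label (e.g. `"SK1"`); used as the contig
#'   prefix in the hybrid reference.
#' @param chromosomes Named character vector of uppercase DNA sequences over
#'   `{A,C,G,T,N}`. Names are chromosome names and must be unique.
#' @return An object of class `StrainGenome` with elements `strain_id` and
#'   `chromosomes`.
#' @examples
#' g <- strain_genome("T", c(chrI = "ACGTACGT"))
#' @export
strain_genome <- function(strain_id, chromosomes) {
  if (!is.character(strain_id) || length(strain_id) != 1L || !nzchar(strain_id))
    stopf("strain_id must be a single non-empty string")
  if (grepl("_", strain_id))
    stopf("strain_id must not contain '_' (reserved as the hybrid contig separator)")
  if (length(chromosomes) == 0L)
    stopf("genome '%s' has no chromosomes", strain_id)
  nm <- names(chromosomes)
  if (is.null(nm) || any(!nzchar(nm)))
    stopf("all chromosomes must be named")
  if (anyDuplicated(nm))
    stopf("duplicate chromosome names in genome '%s'", strain_id)
  if (any(nchar(chromosomes) == 0L))
    stopf("empty chromosome sequence in genome '%s'", strain_id)
  chromosomes <- check_dna(chromosomes, "chromosome")
  structure(list(strain_id = strain_id, chromosomes = chromosomes),
            class = "StrainGenome")
}

#' @export
print.StrainGenome <- function(x, ...) {
  cat(sprintf("StrainGenome '%s': %d chromosome(s), %s bp total\n",
              x$strain_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

genome_length <- function(genome) sum(nchar(genome$chromosomes))

#' Read a strain genome from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param strain_id Strain label to attach.
#' @return A [strain_genome()] object.
#' @export
read_strain_genome <- function(path, strain_id) {
  seqs <- Biostrings::readDNAStringSet(path)
  chrom <- as.character(seqs)
  names(chrom) <- sub("\\s.*$", "", names(seqs))
  strain_genome(strain_id, chrom)
}

#' Write a genome or hybrid reference to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x A `StrainGenome` or `HybridReference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- if (inherits(x, "HybridReference")) x$contigs else x$chromosomes
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Build the concatenated hybrid reference
#'
#' Concatenates the test and spike-in assemblies into one reference in which
#' every contig is named `"<strain_id>_<chromosome>"` and carries its genome
#' of origin. Competitive alignment to this hybrid is what assigns reads to
#' a genome: a read whose sequence occurs at exactly one place in the hybrid
#' must span at least one distinguishing SNP.
#'
#' @param test `StrainGenome` of the test (endogenous) strain.
#' @param spike `StrainGenome` of the spike-in strain.
#' @return A `HybridReference` with elements `contigs` (named character
#'   vector, all test contigs first) and `info` (a `data.table` with columns
#'   `contig`, `origin`, `chrom`, `length`).
#' @export
build_hybrid_reference <- function(test, spike) {
  stopifnot(inherits(test, "StrainGenome"), inherits(spike, "StrainGenome"))
  if (identical(test$strain_id, spike$strain_id))
    stopf("test and spike-in genomes must have different strain_ids (both '%s')",
          test$strain_id)
  for (g in list(test, spike)) {
    n_only <- grepl("^N+$", g$chromosomes)
    if (any(n_only))
      stopf("genome '%s' chromosome '%s' is all-N", g$strain_id,
            names(g$chromosomes)[which(n_only)[1]])
  }
  contigs <- c(
    stats::setNames(test$chromosomes,
                    paste0(test$strain_id, "_", names(test$chromosomes))),
    stats::setNames(spike$chromosomes,
                    paste0(spike$strain_id, "_", names(spike$chromosomes)))
  )
  if (anyDuplicated(names(contigs)))
    stopf("hybrid contig names collide; use distinct strain_ids")
  info <- data.table::data.table(
    contig = names(contigs),
    origin = rep(c("test", "spike"),
                 c(length(test$chromosomes), length(spike$chromosomes))),
    chrom  = c(names(test$chromosomes), names(spike$chromosomes)),
    length = nchar(contigs)
  )
  structure(list(contigs = contigs, info = info), class = "HybridReference")
}

#' @export
print.HybridReference <- function(x, ...) {
  cat(sprintf("HybridReference: %d contigs (%d test + %d spike), %s bp\n",
              nrow(x$info), sum(x$info$origin == "test"),
              sum(x$info$origin == "spike"),
              format(sum(x$info$length), big.mark = ",")))
  invisible(x)
}

#' Construct a SNP map
#'
#' A `SnpMap` lists the positions and alleles that distinguish the two
#' colinear genomes; it is the information source for read assignment.
#' Positions are 0-based. Records are sorted by (chrom, pos) and must be
#' unique.
#'
#' @param records `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (0-based integer), `allele_test`, `allele_spike`.
#' @param genome_length Total number of bases compared (one genome); used
#'   for the divergence diagnostic. `NA` if unknown (e.g. VCF input without
#'   contig lengths).
#' @param chroms Optional character vector of valid chromosome names, used
#'   to validate interval queries.
#' @return A `SnpMap` object.
#' @export
snp_map <- function(records, genome_length = NA_real_, chroms = NULL) {
  rec <- data.table::as.data.table(records)
  need <- c("chrom", "pos", "allele_test", "allele_spike")
  if (!all(need %in% names(rec)))
    stopf("SNP records need columns: %s", paste(need, collapse = ", "))
  rec <- rec[, need, with = FALSE]
  if (nrow(rec)) {
    if (any(rec$allele_test == rec$allele_spike))
      stopf("SNP record with identical test and spike alleles")
    ok <- rec$allele_test %in% c("A", "C", "G", "T") &
          rec$allele_spike %in% c("A", "C", "G", "T")
    if (!all(ok)) stopf("SNP alleles must be in {A,C,G,T}")
    data.table::setorder(rec, chrom, pos)
    if (anyDuplicated(rec, by = c("chrom", "pos")))
      stopf("duplicate (chrom, pos) in SNP records")
  }
  structure(list(records = rec, genome_length = genome_length,
                 chroms = chroms %||% unique(rec$chrom)),
            class = "SnpMap")
}

#' @export
print.SnpMap <- function(x, ...) {
  div <- if (is.na(x$genome_length)) NA_real_ else nrow(x$records) / x$genome_length
  cat(sprintf("SnpMap: %s SNPs on %d chromosome(s)%s\n",
              format(nrow(x$records), big.mark = ","),
              length(unique(x$records$chrom)),
              if (is.na(div)) "" else sprintf(", divergence %.4g", div)))
  invisible(x)
}

#' Derive the SNP map of a colinear, indel-free genome pair
#'
#' For synthetic (or otherwise strictly colinear, equal-length) genome pairs
#' the distinguishing SNPs are exactly the positionwise mismatches. Positions
#' where either genome has an N never yield a record. Real divergent
#' assemblies contain indels and rearrangements; for those, supply an
#' externally produced VCF via [load_snp_map_vcf()].
#'
#' @param test,spike `StrainGenome` objects with identical chromosome names
#'   and per-chromosome lengths.
#' @return A [snp_map()] whose `genome_length` is the total length compared.
#' @export
derive_snp_map <- function(test, spike) {
  stopifnot(inherits(test, "StrainGenome"), inherits(spike, "StrainGenome"))
  if (!identical(names(test$chromosomes), names(spike$chromosomes)))
    stopf("chromosome names differ between genomes; derive_snp_map requires a colinear pair (use load_snp_map_vcf for real assemblies)")
  lt <- nchar(test$chromosomes); ls <- nchar(spike$chromosomes)
  if (any(lt != ls))
    stopf("chromosome '%s' length differs (%d vs %d); derive_snp_map requires an indel-free colinear pair (use load_snp_map_vcf for real assemblies)",
          names(test$chromosomes)[which(lt != ls)[1]],
          lt[which(lt != ls)[1]], ls[which(lt != ls)[1]])
  rawN <- charToRaw("N")
  recs <- lapply(names(test$chromosomes), function(ch) {
    a <- charToRaw(test$chromosomes[[ch]])
    b <- charToRaw(spike$chromosomes[[ch]])
    idx <- which(a != b & a != rawN & b != rawN)
    if (!length(idx)) return(NULL)
    data.table::data.table(
      chrom = ch, pos = idx - 1L,
      allele_test  = strsplit(rawToChar(a[idx]), "")[[1]],
      allele_spike = strsplit(rawToChar(b[idx]), "")[[1]]
    )
  })
  rec <- data.table::rbindlist(recs)
  if (!nrow(rec))
    rec <- data.table::data.table(chrom = character(), pos = integer(),
                                  allele_test = character(),
                                  allele_spike = character())
  snp_map(rec, genome_length = sum(lt), chroms = names(test$chromosomes))
}

#' Load a SNP map from a VCF file
#'
#' Reads biallelic SNP records from a VCF (REF = test allele, single ALT =
#' spike-in allele). Indels and multiallelic records are skipped with a
#' message reporting the count. VCF positions (1-based) are converted to the
#' package-internal 0-based convention.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param genome_length Optional total genome length for the divergence
#'   diagnostic.
#' @return A [snp_map()].
#' @export
load_snp_map_vcf <- function(path, genome_length = NA_real_) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e))
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L) {
    warnf("VCF '%s' has no records; returning an empty SnpMap", path)
    return(snp_map(data.table::data.table(
      chrom = character(), pos = integer(),
      allele_test = character(), allele_spike = character()),
      genome_length = genome_length, chroms = character()))
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  by_chrom <- split(pos1, factor(chrom, levels = unique(chrom)))
  if (any(vapply(by_chrom, is.unsorted, logical(1))))
    stopf("VCF '%s' is not position-sorted within chromosomes", path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(rr))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    ref != alt1
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message(sprintf("load_snp_map_vcf: skipped %d non-SNP/multiallelic record(s)",
                    n_skip))
  snp_map(data.table::data.table(
    chrom = chrom[keep], pos = pos1[keep] - 1L,
    allele_test = ref[keep], allele_spike = alt1[keep]),
    genome_length = genome_length)
}

#' SNP spacing diagnostics
#'
#' Median distance between consecutive SNPs, computed within chromosomes
#' only (never across chromosome boundaries), globally and per chromosome.
#' Dense, evenly spread SNPs are what make the normalization factor robust:
#' the published SK1/S288c pair has ~76,000 SNPs at a median spacing of
#' 70 bp.
#'
#' @param map A [snp_map()]; must be non-empty.
#' @return List with `global_median` (bp), `per_chromosome` (named numeric),
#'   and `count` (number of SNPs). Chromosomes with fewer than two SNPs get
#'   `NA` with a warning.
#' @export
spacing_stats <- function(map) {
  stopifnot(inherits(map, "SnpMap"))
  if (nrow(map$records) == 0L) stopf("spacing_stats: empty SnpMap")
  pos <- split(map$records$pos, map$records$chrom)
  dists <- lapply(pos, function(p) if (length(p) >= 2L) diff(p) else numeric())
  per <- vapply(dists, function(d) if (length(d)) stats::median(d) else NA_real_,
                numeric(1))
  if (anyNA(per))
    warnf("spacing_stats: %d chromosome(s) with a single SNP have no spacing",
          sum(is.na(per)))
  all_d <- unlist(dists, use.names = FALSE)
  gm <- if (length(all_d)) stats::median(all_d) else {
    warnf("spacing_stats: no consecutive SNP pairs anywhere; global median is NA")
    NA_real_
  }
  list(global_median = gm, per_chromosome = per, count = nrow(map$records))
}

#' Restrict a SNP map to peak intervals
#'
#' Keeps the SNP records falling inside any interval of `peaks` (0-based
#' half-open, test-genome coordinates). Used by the peak-restricted pileup
#' estimator, which excludes positions expected to hold only background
#' signal.
#'
#' @param map A [snp_map()].
#' @param peaks A [peak_set()].
#' @return The subsetted [snp_map()].
#' @export
snps_in_intervals <- function(map, peaks) {
  stopifnot(inherits(map, "SnpMap"), inherits(peaks, "PeakSet"))
  if (length(map$chroms)) {
    unknown <- setdiff(unique(peaks$intervals$chrom), map$chroms)
    if (length(unknown))
      stopf("peaks reference unknown chromosome(s): %s",
            paste(unknown, collapse = ", "))
  }
  if (nrow(peaks$intervals) == 0L || nrow(map$records) == 0L)
    return(snp_map(map$records[0L], map$genome_length, map$chroms))
  rec <- map$records
  keep <- logical(nrow(rec))
  for (ch in unique(rec$chrom)) {
    iv <- peaks$intervals[chrom == ch]
    if (!nrow(iv)) next
    ri <- which(rec$chrom == ch)
    # intervals are merged and sorted, so findInterval on starts suffices
    j <- findInterval(rec$pos[ri], iv$start)
    hit <- j > 0L
    hit[hit] <- rec$pos[ri][hit] < iv$end[j[hit]]
    keep[ri] <- hit
  }
  snp_map(rec[keep], map$genome_length, map$chroms)
}

#' Write / read a SNP map as TSV
#'
#' Plain four-column TSV: `chrom`, `pos` (0-based), `allele_test`,
#' `allele_spike`.
#'
#' @param map A [snp_map()].
#' @param path File path.
#' @return `path` (write) or a [snp_map()] (read).
#' @export
write_snp_map <- function(map, path) {
  stopifnot(inherits(map, "SnpMap"))
  data.table::fwrite(map$records, path, sep = "\t")
  invisible(path)
}

#' @rdname write_snp_map
#' @param genome_length,chroms Passed to [snp_map()].
#' @export
read_snp_map <- function(path, genome_length = NA_real_, chroms = NULL) {
  rec <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = c("chrom",
                                                           "allele_test",
                                                           "allele_spike"),
                                             integer = "pos"))
  snp_map(rec, genome_length, chroms)
}
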