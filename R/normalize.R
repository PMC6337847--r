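# The spike-in quotient Q = C_spike / C_endo, the normalization factor
# Nf = Q_Input / Q_ChIP, wild type-normalized condition levels, and the
# end-to-end orchestration across the four estimator variants.

ESTIMATOR_METHODS <- c("read_count", "pileup_all", "pileup_snp",
                       "pileup_snp_peaks")

#' Construct per-sample aggregate counts
#'
#' `C_endo` and `C_spike` are the aggregate signal attributed to the test
#' and the spike-in genome in one sequenced sample — total assigned read
#' counts for the `read_count` method, or a mean pileup score for the three
#' pileup methods.
#'
#' @param sample_role `"ChIP"` or `"Input"`.
#' @param C_endo,C_spike Non-negative scalars.
#' @param method One of `"read_count"`, `"pileup_all"`, `"pileup_snp"`,
#'   `"pileup_snp_peaks"`.
#' @return A `SampleCounts` object.
#' @export
sample_counts <- function(sample_role, C_endo, C_spike,
                          method = "read_count") {
  sample_role <- match.arg(sample_role, c("ChIP", "Input"))
  method <- match.arg(method, ESTIMATOR_METHODS)
  if (!is.numeric(C_endo) || !is.numeric(C_spike) || C_endo < 0 || C_spike < 0)
    stopf("C_endo and C_spike must be non-negative scalars")
  structure(list(sample_role = sample_role, C_endo = C_endo,
                 C_spike = C_spike, method = method),
            class = "SampleCounts")
}

#' Compute the spike-in quotient Q
#'
#' `Q = C_spike / C_endo` for one sample. The input sample's Q reflects the
#' spike-in cell fraction actually present; the ChIP sample's Q additionally
#' reflects the relative per-cell abundance of the target.
#'
#' @param counts A [sample_counts()].
#' @return A `QValue` (list with `value`, `sample_role`, `method`).
#' @export
compute_Q <- function(counts) {
  stopifnot(inherits(counts, "SampleCounts"))
  if (counts$C_endo == 0) stopf("compute_Q: C_endo is 0")
  if (counts$C_spike == 0)
    warnf("compute_Q: C_spike is 0 (no spike-in signal); Q = 0")
  structure(list(value = counts$C_spike / counts$C_endo,
                 sample_role = counts$sample_role, method = counts$method),
            class = "QValue")
}

#' Spike-in cell percentage implied by an input sample's Q
#'
#' `100 * Q / (1 + Q)`: the percentage of the sample comprised of spike-in
#' cells, i.e. the experimental mixing percentage corrected for technical
#' variation. Only meaningful for the non-immunoprecipitated input sample.
#'
#' @param q_input A `QValue` with `sample_role == "Input"`.
#' @return Percentage in `[0, 100)`.
#' @export
spike_in_percentage <- function(q_input) {
  stopifnot(inherits(q_input, "QValue"))
  if (q_input$sample_role != "Input")
    stopf("spike_in_percentage applies to the Input sample's Q only")
  100 * q_input$value / (1 + q_input$value)
}

#' Compute the spike-in normalization factor Nf
#'
#' `Nf = Q_Input / Q_ChIP` for one condition. Multiplying the condition's
#' signal by Nf places all conditions on a common spike-in-anchored scale;
#' because the spike-in's target amount is constant across conditions, Nf
#' ratios are a semi-quantitative measure of target protein amounts.
#'
#' @param q_input,q_chip `QValue`s of the condition's input and ChIP
#'   samples, computed with the same estimator method.
#' @param condition_id Optional condition label.
#' @return A `NormFactor` (list with `value`, `condition_id`, `method`,
#'   `q_input`, `q_chip`).
#' @export
compute_Nf <- function(q_input, q_chip, condition_id = NA_character_) {
  stopifnot(inherits(q_input, "QValue"), inherits(q_chip, "QValue"))
  if (q_input$sample_role != "Input" || q_chip$sample_role != "ChIP")
    stopf("compute_Nf needs an Input-sample Q and a ChIP-sample Q")
  if (!identical(q_input$method, q_chip$method))
    stopf("Q values computed with different methods ('%s' vs '%s')",
          q_input$method, q_chip$method)
  if (q_chip$value == 0)
    stopf("compute_Nf: Q_ChIP is 0 (no spike-in reads in the ChIP sample)")
  if (q_input$value == 0)
    stopf("compute_Nf: Q_Input is 0 (no spike-in signal in the input sample)")
  structure(list(value = q_input$value / q_chip$value,
                 condition_id = condition_id, method = q_input$method,
                 q_input = q_input, q_chip = q_chip),
            class = "NormFactor")
}

#' @export
print.NormFactor <- function(x, ...) {
  cat(sprintf("NormFactor%s [%s]: Nf = %.4g (Q_Input = %.4g, Q_ChIP = %.4g)\n",
              if (is.na(x$condition_id)) "" else paste0(" ", x$condition_id),
              x$method, x$value, x$q_input$value, x$q_chip$value))
  invisible(x)
}

#' Wild type-normalized condition level
#'
#' `level = Nf_condition / Nf_reference`: the target amount in a condition
#' as a fraction of the reference (wild-type) amount. With replicate
#' normalization factors, replicate levels are computed against the mean
#' reference Nf and aggregated as mean with SD.
#'
#' @param nf_cond A `NormFactor` or list of replicate `NormFactor`s.
#' @param nf_wt The reference `NormFactor` (or list of replicates).
#' @return A `ConditionLevel` (list with `condition_id`, `level`,
#'   `replicate_values`, `sd`).
#' @export
relative_level <- function(nf_cond, nf_wt) {
  as_list <- function(x) if (inherits(x, "NormFactor")) list(x) else x
  nf_cond <- as_list(nf_cond); nf_wt <- as_list(nf_wt)
  stopifnot(all(vapply(nf_cond, inherits, logical(1), "NormFactor")),
            all(vapply(nf_wt, inherits, logical(1), "NormFactor")))
  meths <- unique(vapply(c(nf_cond, nf_wt), `[[`, character(1), "method"))
  if (length(meths) != 1L)
    stopf("relative_level: mixed estimator methods (%s)",
          paste(meths, collapse = ", "))
  wt <- mean(vapply(nf_wt, `[[`, numeric(1), "value"))
  if (wt <= 0) stopf("relative_level: reference Nf must be > 0")
  reps <- vapply(nf_cond, `[[`, numeric(1), "value") / wt
  structure(list(condition_id = nf_cond[[1]]$condition_id,
                 level = mean(reps), replicate_values = reps,
                 sd = if (length(reps) > 1L) stats::sd(reps) else NA_real_),
            class = "ConditionLevel")
}

#' @export
print.ConditionLevel <- function(x, ...) {
  cat(sprintf("ConditionLevel%s: %.1f%% of reference%s (%d replicate(s))\n",
              if (is.na(x$condition_id)) "" else paste0(" ", x$condition_id),
              100 * x$level,
              if (is.na(x$sd)) "" else sprintf(" +/- %.1f%% (SD)", 100 * x$sd),
              length(x$replicate_values)))
  invisible(x)
}

#' Aggregate signal per genome under one estimator method
#'
#' The `read_count` method uses the assigned read counts directly. The three
#' pileup methods replace the counts by mean coverage scores: over every
#' base (`pileup_all`), over SNP positions only (`pileup_snp`), or over SNP
#' positions inside peaks (`pileup_snp_peaks`). Colinearity of the synthetic
#' pair lets the same SNP coordinates (and the peak restriction, defined on
#' test coordinates) index both genomes.
#'
#' @param method One of the four estimator methods.
#' @param assignment An [assign_reads()] result.
#' @param snpmap [snp_map()]; required for the SNP-restricted methods.
#' @param peaks [peak_set()]; required for `pileup_snp_peaks`.
#' @param read_length Read length for pileup construction; defaults to the
#'   assignment's.
#' @param sample_role `"ChIP"` or `"Input"` label carried into the result.
#' @return A [sample_counts()].
#' @export
estimate_counts <- function(method, assignment, snpmap = NULL, peaks = NULL,
                            read_length = NULL, sample_role = "ChIP") {
  method <- match.arg(method, ESTIMATOR_METHODS)
  stopifnot(inherits(assignment, "AssignmentResult"))
  if (method == "read_count")
    return(sample_counts(sample_role, assignment$C_endo, assignment$C_spike,
                         method))
  if (method %in% c("pileup_snp", "pileup_snp_peaks") && is.null(snpmap))
    stopf("method '%s' requires a SnpMap", method)
  if (method == "pileup_snp_peaks" && is.null(peaks))
    stopf("method 'pileup_snp_peaks' requires a PeakSet")
  mode <- switch(method, pileup_all = "all", pileup_snp = "snp",
                 pileup_snp_peaks = "snp_peaks")
  tt <- pileup_from_assignment(assignment, read_length, "test")
  ts <- pileup_from_assignment(assignment, read_length, "spike")
  sample_counts(sample_role,
                mean_pileup(tt, mode, snpmap = snpmap, peaks = peaks),
                mean_pileup(ts, mode, snpmap = snpmap, peaks = peaks),
                method)
}

#' Run the full normalization workflow over several conditions
#'
#' For every condition: classify reads on the hybrid (or ingest a
#' per-contig count table), estimate `C_endo`/`C_spike`, form `Q_Input` and
#' `Q_ChIP`, compute `Nf`, and express each condition's level relative to
#' the reference condition. Optionally writes spike-in-scaled (and
#' SPMR-scaled) bedGraph tracks and a JSON report.
#'
#' @param conditions Named list; each element a list with `chip` and
#'   `input` ([read_set()]s, or paths to per-contig count tables for the
#'   table-only workflow) and optionally `reference = TRUE` (exactly one
#'   condition must be the reference).
#' @param hybrid [build_hybrid_reference()]; required when reads are given.
#' @param snpmap,peaks Passed to [estimate_counts()] for pileup methods.
#' @param method Estimator method (default `"read_count"`, the recommended
#'   approximation).
#' @param read_length Read length for pileup construction.
#' @param index Optional prebuilt [build_exact_index()] (reused across
#'   conditions).
#' @param emit_tracks If `TRUE`, attach SPMR- and Nf-scaled test-genome
#'   ChIP tracks.
#' @param out_dir If non-`NULL`, write `report.json` and per-condition
#'   bedGraph tracks there.
#' @return A `NormalizationReport`: per-condition list with `counts`, `Q`,
#'   `Nf`, `level`, `spike_pct`, plus `reference` and `method`.
#' @export
normalize_experiment <- function(conditions, hybrid = NULL, snpmap = NULL,
                                 peaks = NULL, method = "read_count",
                                 read_length = NULL, index = NULL,
                                 emit_tracks = FALSE, out_dir = NULL) {
  method <- match.arg(method, ESTIMATOR_METHODS)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stopf("conditions must be a named list")
  is_ref <- vapply(conditions, function(x) isTRUE(x$reference), logical(1))
  if (sum(is_ref) != 1L)
    stopf("exactly one condition must have reference = TRUE (found %d)",
          sum(is_ref))
  ref_id <- names(conditions)[is_ref]

  per_cond <- list()
  for (cid in names(conditions)) {
    cond <- conditions[[cid]]
    if (is.null(cond$chip) || is.null(cond$input))
      stopf("condition '%s' must supply both chip and input samples (Nf requires Q_Input)",
            cid)
    samples <- list()
    for (role in c("ChIP", "Input")) {
      x <- if (role == "ChIP") cond$chip else cond$input
      if (is.character(x)) {          # per-contig count table path
        if (method != "read_count")
          stopf("condition '%s': count-table input supports only method 'read_count' (pileup methods need per-read placements)",
                cid)
        if (is.null(hybrid) && is.null(index))
          stopf("a hybrid reference (or index) is needed to resolve contig origins")
        info <- if (!is.null(index)) index$info else hybrid$info
        cnt <- counts_from_contig_table(
          x, stats::setNames(info$origin, info$contig))
        samples[[role]] <- list(
          counts = sample_counts(role, cnt$C_endo, cnt$C_spike, method),
          assignment = NULL)
      } else if (inherits(x, "AssignmentResult")) {
        samples[[role]] <- list(
          counts = estimate_counts(method, x, snpmap, peaks, read_length,
                                   sample_role = role),
          assignment = x)
      } else {
        if (is.null(index)) {
          if (is.null(hybrid)) stopf("reads supplied but no hybrid reference")
          index <- build_exact_index(
            hybrid, read_length %||% nchar(x$seq[1L]))
        }
        asg <- assign_reads(x, index)
        samples[[role]] <- list(
          counts = estimate_counts(method, asg, snpmap, peaks, read_length,
                                   sample_role = role),
          assignment = asg)
      }
    }
    q_in <- compute_Q(samples$Input$counts)
    q_ch <- compute_Q(samples$ChIP$counts)
    pct <- spike_in_percentage(q_in)
    warn <- character()
    if (pct < 15) {
      warn <- sprintf("estimated spike-in percentage %.1f%% < 15%%; low spike-in fractions inflate noise",
                      pct)
      warnf("condition '%s': %s", cid, warn)
    }
    nf <- compute_Nf(q_in, q_ch, condition_id = cid)
    per_cond[[cid]] <- list(samples = samples, q_input = q_in, q_chip = q_ch,
                            nf = nf, spike_pct = pct, warnings = warn)
  }

  nf_ref <- per_cond[[ref_id]]$nf
  for (cid in names(per_cond))
    per_cond[[cid]]$level <- relative_level(per_cond[[cid]]$nf, nf_ref)

  if (emit_tracks || !is.null(out_dir)) {
    for (cid in names(per_cond)) {
      asg <- per_cond[[cid]]$samples$ChIP$assignment
      if (is.null(asg)) next
      tr <- pileup_from_assignment(asg, read_length, "test")
      tr <- spmr_scale(tr, asg$C_endo + asg$C_spike)
      tr <- apply_norm_factor(tr, per_cond[[cid]]$nf)
      per_cond[[cid]]$track <- tr
    }
  }

  res <- structure(list(conditions = per_cond, reference = ref_id,
                        method = method), class = "NormalizationReport")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_json(res),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cid in names(per_cond))
      if (!is.null(per_cond[[cid]]$track))
        write_bedgraph(per_cond[[cid]]$track,
                       file.path(out_dir, paste0(cid, "_scaled.bedgraph")))
  }
  res
}

# Machine-readable report payload.
report_json <- function(report) {
  stopifnot(inherits(report, "NormalizationReport"))
  list(
    reference = report$reference,
    method = report$method,
    conditions = lapply(report$conditions, function(pc) list(
      samples = lapply(pc$samples, function(s) list(
        C_endo = s$counts$C_endo, C_spike = s$counts$C_spike)),
      Q_input = pc$q_input$value,
      Q_chip = pc$q_chip$value,
      Nf = pc$nf$value,
      spike_in_percentage = pc$spike_pct,
      level_vs_reference = pc$level$level,
      warnings = pc$warnings))
  )
}

#' @export
print.NormalizationReport <- function(x, ...) {
  cat(sprintf("NormalizationReport [%s], reference '%s':\n", x$method,
              x$reference))
  for (cid in names(x$conditions)) {
    pc <- x$conditions[[cid]]
    cat(sprintf("  %-12s Nf = %.4g  level = %.1f%%  spike-in = %.1f%%\n",
                cid, pc$nf$value, 100 * pc$level$level, pc$spike_pct))
  }
  invisible(x)
}
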