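# Robustness analyses: sequencing-depth subsampling grids for the stability
# of the normalization factor, and spike-in titration linearity.

#' Uniform read subsample without replacement
#'
#' @param reads A [read_set()].
#' @param n Subsample size (`0 <= n <= |reads|`).
#' @param seed Integer seed; the draw is deterministic for a fixed seed.
#' @return A [read_set()] of `n` reads.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (n > NROW(reads))
    stopf("cannot subsample %d from %d reads", n, NROW(reads))
  if (n == 0L) return(reads[0L])
  idx <- with_seed(seed, sample.int(NROW(reads), n))
  reads[idx]
}

#' Ordinary least-squares line fit
#'
#' Diagnostic fit used by the depth-linearity and titration analyses.
#' When all y are identical (`SS_tot = 0`) the fit is exact by convention
#' and `r_squared = 1`.
#'
#' @param x,y Numeric vectors (or `points`, a two-column object).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[[2]]; x <- x[[1]] }
  if (length(x) != length(y) || length(x) < 2L)
    stopf("linear_fit needs >= 2 points")
  if (length(unique(x)) < 2L) stopf("linear_fit: degenerate x (all equal)")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

#' Depth-subsampling grid for the wild type-normalized level
#'
#' Mirrors the published robustness design: subsample each of the four
#' samples (reference ChIP/input, condition ChIP/input) to every size in
#' `sizes`, then compute the condition's wild type-normalized level for
#' every cross-sample size combination (`|sizes|^4` values). Because
#' classification is per-read and deterministic, each full sample is
#' classified once and subsets are drawn from the per-read calls —
#' equivalent to subsampling raw reads first. Subset seeds derive from
#' `(seed, sample, size)` so the grid is reproducible.
#'
#' @param samples Named list with `wt_chip`, `wt_input`, `mut_chip`,
#'   `mut_input`, each either a [read_set()] (requires `index`) or a
#'   pre-computed [assign_reads()] result.
#' @param sizes Subsample sizes (reads per sample).
#' @param seed Master seed.
#' @param index [build_exact_index()]; needed when `samples` are read sets.
#' @param method Estimator; the grid supports `"read_count"` (the method
#'   the published grid used; pileup variants would need a track rebuild
#'   per combination).
#' @return A `SubsampleGrid`: `nf_values` (levels, one per combination),
#'   `summary` (mean, sd, cv), `aligned` (`data.table` sample/size/aligned
#'   read count for the depth-linearity check), and `sizes`.
#' @export
nf_subsample_grid <- function(samples, sizes, seed = 1L, index = NULL,
                              method = "read_count") {
  need <- c("wt_chip", "wt_input", "mut_chip", "mut_input")
  if (!all(need %in% names(samples)))
    stopf("samples must be a named list with: %s", paste(need, collapse = ", "))
  if (method != "read_count")
    stopf("nf_subsample_grid supports method 'read_count' only")
  if (!length(sizes)) stopf("sizes must be non-empty")
  sizes <- sort(as.integer(sizes))
  calls <- lapply(need, function(nm) {
    x <- samples[[nm]]
    if (inherits(x, "AssignmentResult")) x$per_read$call
    else {
      if (is.null(index)) stopf("read-set samples require an index")
      assign_reads(x, index)$per_read$call
    }
  })
  names(calls) <- need
  too_big <- sizes[sizes > min(vapply(calls, length, integer(1)))]
  if (length(too_big))
    stopf("subsample size %d exceeds the smallest sample", too_big[1])

  # per (sample, size): C_endo, C_spike, aligned count on a seeded subset
  per <- lapply(need, function(nm) {
    lapply(seq_along(sizes), function(si) {
      idx <- with_seed(derive_seed(seed, nm, sizes[si]),
                       sample.int(length(calls[[nm]]), sizes[si]))
      cl <- calls[[nm]][idx]
      list(C_endo = sum(cl == "test"), C_spike = sum(cl == "spike"))
    })
  })
  names(per) <- need
  aligned <- data.table::rbindlist(lapply(need, function(nm)
    data.table::data.table(
      sample = nm, size = sizes,
      aligned = vapply(per[[nm]], function(p) p$C_endo + p$C_spike,
                       numeric(1)))))

  grid <- expand.grid(wt_chip = seq_along(sizes), wt_input = seq_along(sizes),
                      mut_chip = seq_along(sizes),
                      mut_input = seq_along(sizes))
  q_of <- function(nm, si, role) {
    p <- per[[nm]][[si]]
    compute_Q(sample_counts(role, p$C_endo, p$C_spike, "read_count"))
  }
  nf_values <- vapply(seq_len(nrow(grid)), function(i) {
    nf_wt <- compute_Nf(q_of("wt_input", grid$wt_input[i], "Input"),
                        q_of("wt_chip", grid$wt_chip[i], "ChIP"), "wt")
    nf_mut <- compute_Nf(q_of("mut_input", grid$mut_input[i], "Input"),
                         q_of("mut_chip", grid$mut_chip[i], "ChIP"), "mut")
    relative_level(nf_mut, nf_wt)$level
  }, numeric(1))

  sdv <- if (length(nf_values) > 1L) stats::sd(nf_values) else 0
  structure(list(
    nf_values = nf_values,
    summary = list(mean = mean(nf_values), sd = sdv,
                   cv = sdv / mean(nf_values)),
    aligned = aligned, sizes = sizes), class = "SubsampleGrid")
}

#' @export
print.SubsampleGrid <- function(x, ...) {
  cat(sprintf("SubsampleGrid: %d combinations over sizes {%s}; level = %.4g +/- %.2g (CV %.2f%%)\n",
              length(x$nf_values), paste(x$sizes, collapse = ", "),
              x$summary$mean, x$summary$sd, 100 * x$summary$cv))
  invisible(x)
}

#' Spike-in titration series
#'
#' Simulates one input + ChIP sample pair per spike-in cell fraction and
#' records the spike read proportion in each (among assigned reads), the
#' least-squares fit of ChIP versus input proportions — linearity of this
#' relationship is what makes the method independent of the amount of
#' spike-in material — and the per-fraction normalization factor.
#'
#' @param base_config A [sim_config()]; its `spike_fraction` is replaced by
#'   each value of `fractions` in turn (genomes and profile stay fixed).
#' @param fractions At least three spike-in cell fractions in `(0, 1)`.
#' @param seed Master seed (overrides `base_config$seed`).
#' @param condition_id Condition to titrate (default: first abundance
#'   entry).
#' @return A `TitrationResult`: `points` (`data.table` with
#'   `input_spike_fraction`, `chip_spike_fraction`), `slope`, `intercept`,
#'   `r_squared`, `per_point_Nf`, `expected_Nf`.
#' @export
titration_series <- function(base_config, fractions, seed = NULL,
                             condition_id = NULL) {
  stopifnot(inherits(base_config, "SimConfig"))
  if (length(fractions) < 3L)
    stopf("titration needs >= 3 fractions (fit underdetermined)")
  if (any(fractions <= 0 | fractions >= 1))
    stopf("fractions must lie in (0, 1)")
  condition_id <- condition_id %||% names(base_config$abundance)[1]
  if (!is.null(seed)) base_config$seed <- as.integer(seed)
  world <- sim_world(base_config)
  index <- build_exact_index(build_hybrid_reference(world$test, world$spike),
                             base_config$read_length)
  pts <- data.table::data.table(input_spike_fraction = numeric(),
                                chip_spike_fraction = numeric())
  nfs <- numeric()
  for (fr in fractions) {
    cfg <- base_config
    cfg$spike_fraction <- fr
    cfg$seed <- derive_seed(base_config$seed, "titration", fr)
    w <- world; w$config <- cfg
    frac_of <- function(role) {
      asg <- assign_reads(simulate_reads(cfg, condition_id, role, w)$reads,
                          index)
      list(frac = asg$C_spike / (asg$C_endo + asg$C_spike), asg = asg)
    }
    fin <- frac_of("Input"); fch <- frac_of("ChIP")
    pts <- rbind(pts, data.table::data.table(
      input_spike_fraction = fin$frac, chip_spike_fraction = fch$frac))
    nf <- compute_Nf(
      compute_Q(sample_counts("Input", fin$asg$C_endo, fin$asg$C_spike)),
      compute_Q(sample_counts("ChIP", fch$asg$C_endo, fch$asg$C_spike)),
      condition_id)
    nfs <- c(nfs, nf$value)
  }
  fit <- linear_fit(pts$input_spike_fraction, pts$chip_spike_fraction)
  if (abs(fit$slope) < 1e-3)
    warnf("titration slope ~ 0: ChIP spike fraction does not respond to input fraction (pathological)")
  structure(c(list(points = pts, per_point_Nf = nfs, fractions = fractions,
                   expected_Nf = expected_values(base_config, condition_id,
                                                 world)$Nf),
              fit),
            class = "TitrationResult")
}

#' @export
print.TitrationResult <- function(x, ...) {
  cat(sprintf("TitrationResult: %d fractions; chip ~ input slope %.3g, R^2 = %.4f\n",
              nrow(x$points), x$slope, x$r_squared))
  invisible(x)
}
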