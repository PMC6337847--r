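# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' seeded internals never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and labels
#'
#' Each (sample, condition, role, ...) combination gets its own RNG stream so
#' adding conditions to a design never perturbs existing samples. The result
#' is always a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param ... Character/numeric labels identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 2147483647
  as.integer(((as.numeric(master) %% 2147483647) * 48271 + h) %% 2147483647)
}

# Fast random DNA string of length n (uppercase, no N).
random_dna <- function(n) {
  bases <- charToRaw("ACGT")
  rawToChar(bases[sample.int(4L, n, replace = TRUE)])
}

# Vectorized reverse complement for character sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA alphabet ({A,C,G,T,N}); returns uppercased sequences.
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stopf("%s %s contains characters outside {A,C,G,T%s}",
          what, which(bad)[1], if (allow_n) ",N" else "")
  x
}
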