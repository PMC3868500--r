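#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used throughout the package's report columns (base R's
#' `round()` rounds ties to even). A small epsilon guards against binary
#' representation artifacts such as `0.285 * 100 == 28.499999...`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up (away from zero).
#' @examples
#' round_half_up(c(0.125, -0.125, 2.5), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACCGT")
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Tag sequences are held internally in the DNA alphabet (U normalized to
#' T); miRNA-facing reports render them in RNA, matching the convention of
#' mature-miRNA databases.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the target alphabet, uppercased.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Run code with a private, seeded RNG stream; the caller's global
# .Random.seed is restored on exit so no simulation leaks state.
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate that sequences use the DNA alphabet only.
check_alphabet <- function(x, allow_n = FALSE, what = "sequence") {
  pattern <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pattern, x))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s %s contains characters outside the %s alphabet",
      what, bad[1], if (allow_n) "A/C/G/T/N" else "A/C/G/T"
    ))
  }
  invisible(x)
}

# Mean Phred score per read, computed in one pass over the concatenated
# quality strings (Sanger / Phred+33 encoding).
phred_means <- function(quality) {
  n <- nchar(quality)
  if (length(quality) == 0) return(numeric())
  if (any(n == 0)) rlang::abort("empty quality string")
  ints <- utf8ToInt(paste(quality, collapse = "")) - 33L
  idx <- rep.int(seq_along(quality), n)
  as.numeric(rowsum(ints, idx)) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
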