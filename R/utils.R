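#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 32-bit child seed for a named pipeline stage.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

#' Truncate a fraction to a one-decimal percentage
#'
#' Converts a proportion to a percentage reported with one decimal place,
#' truncating (not rounding) the second decimal.  This reproduces the
#' printed background-filter percentages exactly (e.g. 820/1686 -> 48.6,
#' 119/156 -> 76.2).
#'
#' @param x numeric proportion(s) in \[0, 1\].
#' @return numeric percentage(s) with one decimal digit.
#' @export
percent_1dp <- function(x) {
  floor(x * 1000 + 1e-9) / 10
}

# Reverse complement of a plain character string.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a codon string to a single-letter amino acid ("*" for stop).
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() without the scalar-x surprise (sample(5, 1) draws from 1:5)
resample <- function(x, size, ...) {
  x[sample.int(length(x), size, ...)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
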