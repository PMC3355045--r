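#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_int map2 imap pmap keep
#' @importFrom stats median sd var cor prcomp glm binomial pchisq quantile
#'   rnorm runif rbinom rpois t.test wilcox.test cor.test setNames complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# Base codes used throughout: A=1, C=2, G=3, T=4, anything else (N, gap) = 0.
BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-stream seed from a master seed and a stage name
#'
#' All randomness in the package flows through one user-supplied master seed;
#' each pipeline stage draws from its own named sub-stream so stages can be
#' re-run independently without perturbing one another.
#'
#' @param seed Master integer seed.
#' @param name Character tag of the sub-stream (e.g. "synthesis", "cv_folds").
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# internal: run code under a named sub-stream of the master seed
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical representative of a word: lexicographic min of word and revcomp
canonical_word <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# all k-mers over ACGT in lexicographic order
all_words <- function(k) {
  sort(Biostrings::mkAllStrings(BASES, k))
}

# sequences -> integer matrix (n x max_len), codes A=1..T=4, other 0;
# rows padded with 0 beyond each sequence's length
seqs_to_intmat <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  lens <- nchar(seqs)
  wmax <- max(lens)
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  m <- matrix(0L, nrow = length(seqs), ncol = wmax)
  for (i in seq_along(seqs)) {
    if (lens[i] > 0L) m[i, seq_len(lens[i])] <- code[utf8ToInt(seqs[i])]
  }
  attr(m, "lens") <- lens
  m
}

# sample a random DNA string from base probabilities (uses current RNG state)
random_dna <- function(n, base_probs) {
  paste(sample(BASES, n, replace = TRUE, prob = base_probs), collapse = "")
}
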