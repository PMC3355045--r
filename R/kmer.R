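# Sequence-word (k-mer) profiling: merged-complement counting, frequency
# matrices, AT normalization and scaling.
#
# Frequencies follow the count/L convention: every window sliding one
# nucleotide at a time is counted (windows containing N are skipped) and the
# merged count of a word and its reverse complement is divided by the full
# sequence length, not by L - k + 1.

# per-k lookup tables: word labels, reverse-complement index, palindrome mask,
# canonical mask, per-letter composition counts
word_tables <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    words <- all_words(k)
    rc <- revcomp(words)
    tab <- list(
      words = words,
      rc_idx = match(rc, words),
      palindrome = rc == words,
      canonical = words <= rc,
      letter_counts = {
        mat <- matrix(0L, length(words), 4L, dimnames = list(words, BASES))
        sp <- strsplit(words, "", fixed = TRUE)
        for (b in 1:4) mat[, b] <- vapply(sp, function(s) sum(s == BASES[b]), 0L)
        mat
      }
    )
    cache[[key]] <<- tab
    tab
  }
})

#' Count sequence words with reverse-complement merging
#'
#' Slides a window of width `k` one nucleotide at a time over `sequence`;
#' windows containing only A/C/G/T each increment one canonical word (the
#' lexicographic minimum of the word and its reverse complement); windows
#' containing any other letter (N) are skipped.
#'
#' @param sequence A single DNA string.
#' @param k Word length, between 2 and 6.
#' @return Named integer vector of counts over canonical words (zero counts
#'   dropped).
#' @examples
#' count_words("ACGT", 2)  # GT merges into AC
#' @export
count_words <- function(sequence, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > 6) {
    abort("`k` must be a single integer in [2, 6].", class = "mslseq_parameter_error")
  }
  cnt <- merged_count_matrix(sequence, as.integer(k))[1L, ]
  cnt <- cnt[cnt > 0L]
  cnt[order(names(cnt))]
}

# raw (unmerged) count matrix over all 4^k words; rows = sequences or pooled
# observations given as a list of character vectors
raw_count_matrix <- function(seqs, k) {
  if (is.character(seqs)) seqs <- as.list(seqs)
  pooled <- vapply(seqs, length, 0L)
  flat <- Biostrings::DNAStringSet(toupper(unlist(seqs, use.names = FALSE)))
  cnt <- Biostrings::oligonucleotideFrequency(flat, width = k)
  # sum member rows per pooled observation (no junction words are ever counted)
  grp <- rep(seq_along(seqs), pooled)
  out <- rowsum(cnt, grp, reorder = TRUE)
  storage.mode(out) <- "integer"
  colnames(out) <- colnames(cnt)
  out
}

# merged (canonical) integer count matrix, columns = canonical words of width k
merged_count_matrix <- function(seqs, k) {
  tab <- word_tables(k)
  cnt <- raw_count_matrix(seqs, k)
  cnt <- cnt[, tab$words, drop = FALSE]
  merged <- cnt + cnt[, tab$rc_idx, drop = FALSE]
  merged[, tab$palindrome] <- cnt[, tab$palindrome, drop = FALSE]
  merged[, tab$canonical, drop = FALSE]
}

#' Word frequency vector for one sequence
#'
#' @param sequence A single DNA string (length >= `k_max`).
#' @param k_min,k_max Word length range (defaults 2 and 6).
#' @param layout `"as_published"` mirrors each merged value into both the word
#'   and reverse-complement columns (5456 columns for k = 2..6);
#'   `"canonical"` keeps one column per complement-equivalence class.
#' @return Named numeric vector of merged count / sequence length.
#' @export
word_frequencies <- function(sequence, k_min = 2, k_max = 6,
                             layout = c("as_published", "canonical")) {
  layout <- match.arg(layout)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be one non-empty string.", class = "mslseq_input_error")
  }
  if (nchar(sequence) < k_max) {
    abort("`sequence` shorter than `k_max`.", class = "mslseq_input_error")
  }
  frequency_matrix(list(sequence), k_min, k_max, layout)[1L, ]
}

# frequency matrix over a list of (possibly pooled) observations
frequency_matrix <- function(seqs, k_min, k_max, layout) {
  if (is.character(seqs)) seqs <- as.list(seqs)
  lens <- vapply(seqs, function(s) sum(nchar(s)), 0)
  blocks <- lapply(seq(k_min, k_max), function(k) {
    tab <- word_tables(k)
    merged <- merged_count_matrix(seqs, k)
    freq <- merged / lens
    if (layout == "canonical") return(freq)
    # mirror merged values into both complement columns
    canon <- canonical_word(tab$words)
    out <- freq[, canon, drop = FALSE]
    colnames(out) <- tab$words
    out
  })
  do.call(cbind, blocks)
}

#' Expected merged frequency of a word under i.i.d. bases
#'
#' The expectation of a word w under independent bases is the product of its
#' letter probabilities; the merged expectation adds the reverse complement's
#' unless the word is self-complementary. Base probabilities are floored at
#' 1e-6 before the product so degenerate compositions stay finite.
#'
#' @param word A DNA word (2-6 bp).
#' @param base_probs Numeric 4-vector of A,C,G,T probabilities summing to 1.
#' @return Expected merged per-window frequency.
#' @examples
#' expected_frequency("AA", rep(0.25, 4))  # 0.125: AA merged with TT
#' @export
expected_frequency <- function(word, base_probs) {
  stopifnot(length(base_probs) == 4L, abs(sum(base_probs) - 1) < 1e-6)
  p <- pmax(as.numeric(base_probs), 1e-6)
  names(p) <- BASES
  ew <- function(w) prod(p[strsplit(w, "", fixed = TRUE)[[1L]]])
  rc <- revcomp(word)
  if (rc == word) ew(word) else ew(word) + ew(rc)
}

#' Build a word-frequency matrix from sequences
#'
#' Observations are single sequences or pooled groups (a named list whose
#' elements are character vectors of member sequences); pooled counts are the
#' sums over members and the denominator is the summed member length, so no
#' junction-spanning words are ever counted.
#'
#' @param x Named character vector, named list of character vectors, or a data
#'   frame with columns `obs_id` and `bases` (rows sharing an `obs_id` are
#'   pooled).
#' @param k_min,k_max Word length range.
#' @param layout `"as_published"` (both complement columns, 5456 variables for
#'   k = 2..6) or `"canonical"` (one column per complement class).
#' @return A `word_matrix`: numeric matrix with attributes tracking the
#'   normalization/scaling state, layout, and each observation's base
#'   composition (used by [at_normalize()]).
#' @export
word_matrix <- function(x, k_min = 2, k_max = 6,
                        layout = c("as_published", "canonical")) {
  layout <- match.arg(layout)
  stopifnot(k_min >= 2, k_max <= 6, k_min <= k_max)
  if (is.data.frame(x)) {
    stopifnot(all(c("obs_id", "bases") %in% names(x)))
    x <- split(x$bases, factor(x$obs_id, levels = unique(x$obs_id)))
  }
  if (is.character(x)) x <- as.list(x)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    abort("observations must have unique names", class = "mslseq_input_error")
  }
  lens <- vapply(x, function(s) sum(nchar(s)), 0)
  if (any(lens < k_max)) {
    abort("every observation must be at least `k_max` bases long",
          class = "mslseq_input_error")
  }
  mono <- raw_count_matrix(x, 1L)[, BASES, drop = FALSE]
  m <- frequency_matrix(x, k_min, k_max, layout)
  rownames(m) <- names(x)
  structure(
    m,
    class = c("word_matrix", "matrix", "array"),
    state_norm = "raw", state_scale = "unscaled",
    layout = layout, k_min = k_min, k_max = k_max,
    base_counts = mono, seq_len = lens, col_stats = NULL
  )
}

#' @export
print.word_matrix <- function(x, ...) {
  cat(sprintf(
    "<word_matrix> %d observations x %d words (k=%d..%d, %s layout; %s, %s)\n",
    nrow(x), ncol(x), attr(x, "k_min"), attr(x, "k_max"), attr(x, "layout"),
    attr(x, "state_norm"), attr(x, "state_scale")
  ))
  invisible(x)
}

#' Per-observation AT content of a word matrix
#' @param wm A `word_matrix`.
#' @return Numeric vector, fraction of A+T per observation.
#' @export
at_content <- function(wm) {
  bc <- attr(wm, "base_counts")
  (bc[, "A"] + bc[, "T"]) / rowSums(bc)
}

# expected-frequency matrix matching the columns of a word matrix
expected_matrix <- function(wm) {
  bc <- attr(wm, "base_counts")
  probs <- pmax(bc / rowSums(bc), 1e-6)
  layout <- attr(wm, "layout")
  blocks <- lapply(seq(attr(wm, "k_min"), attr(wm, "k_max")), function(k) {
    tab <- word_tables(k)
    logE <- tab$letter_counts %*% t(log(probs))   # 4^k x n
    E <- exp(logE)
    Emerged <- E + E[tab$rc_idx, , drop = FALSE]
    Emerged[tab$palindrome, ] <- E[tab$palindrome, , drop = FALSE]
    keep <- if (layout == "canonical") tab$canonical else rep(TRUE, length(tab$words))
    t(Emerged[keep, , drop = FALSE])
  })
  out <- do.call(cbind, blocks)
  dimnames(out) <- dimnames(wm)
  out
}

#' AT-normalize a word matrix
#'
#' Divides each word frequency by its expected frequency under the
#' observation's own mononucleotide composition (independent-base model), so
#' that variation driven purely by AT content is removed before multivariate
#' analysis.
#'
#' @param wm A raw `word_matrix`.
#' @return The matrix of observed/expected ratios, state `at_normalized`.
#' @export
at_normalize <- function(wm) {
  stopifnot(inherits(wm, "word_matrix"))
  if (attr(wm, "state_norm") != "raw") {
    abort("matrix is already AT-normalized", class = "mslseq_state_error")
  }
  out <- wm / expected_matrix(wm)
  attributes(out) <- attributes(wm)
  attr(out, "state_norm") <- "at_normalized"
  out
}

#' Center or unit-variance scale a word matrix
#'
#' AT-normalized matrices are center-scaled; raw matrices are unit-variance
#' (UV) scaled (centered and divided by the column standard deviation;
#' zero-variance columns are left at zero).
#'
#' @param wm A `word_matrix`.
#' @param mode `"centered"` (requires state `at_normalized`) or `"uv_scaled"`
#'   (requires state `raw`).
#' @return The scaled matrix; column means/SDs are stored in the `col_stats`
#'   attribute so the identical scaling can be applied to new observations.
#' @export
scale_matrix <- function(wm, mode = c("centered", "uv_scaled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wm, "word_matrix"))
  if (attr(wm, "state_scale") != "unscaled") {
    abort("matrix is already scaled", class = "mslseq_state_error")
  }
  norm <- attr(wm, "state_norm")
  if (mode == "centered" && norm != "at_normalized") {
    abort("center scaling is reserved for AT-normalized data; use uv_scaled",
          class = "mslseq_state_error")
  }
  if (mode == "uv_scaled" && norm != "raw") {
    abort("UV scaling is reserved for raw frequencies; use centered",
          class = "mslseq_state_error")
  }
  mu <- colMeans(wm)
  if (mode == "centered") {
    sdv <- rep(1, ncol(wm))
  } else {
    sdv <- apply(wm, 2L, sd)
    sdv[sdv == 0] <- Inf   # zero-variance columns scale to exactly 0
  }
  out <- sweep(sweep(unclass(wm), 2L, mu, "-"), 2L, sdv, "/")
  attributes(out) <- attributes(wm)
  attr(out, "state_scale") <- mode
  attr(out, "col_stats") <- list(mean = mu, sd = sdv, mode = mode, norm = norm)
  out
}

# apply a fitted matrix's column scaling to new raw/at-normalized data
apply_col_stats <- function(m, col_stats) {
  if (!all(names(col_stats$mean) %in% colnames(m))) {
    abort("new data lack variables of the fitted matrix",
          class = "mslseq_schema_error")
  }
  m <- m[, names(col_stats$mean), drop = FALSE]
  sweep(sweep(m, 2L, col_stats$mean, "-"), 2L, col_stats$sd, "/")
}

#' @rdname word_matrix
#' @param path File path for the TSV round-trip of a word matrix.
#' @param wm A `word_matrix` to write.
#' @export
write_word_matrix <- function(wm, path) {
  hdr <- sprintf("# mslseq word_matrix state=%s scale=%s layout=%s k=%d..%d",
                 attr(wm, "state_norm"), attr(wm, "state_scale"),
                 attr(wm, "layout"), attr(wm, "k_min"), attr(wm, "k_max"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(obs_id = rownames(wm), unclass(wm), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-format view of a word matrix
#'
#' @param x A `word_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `obs_id`, `word`, `value`.
#' @export
tidy.word_matrix <- function(x, ...) {
  tibble(
    obs_id = rep(rownames(x), times = ncol(x)),
    word = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}
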