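# Iterative word-to-PWM motif builder: discriminative sequence words (ranked
# by OPLS-DA loading) are aligned into position weight matrices. A PWM is
# seeded from the top word, every unconsumed word is tested for extension in
# both orientations at all admissible offsets, and each update must pass a
# logistic-regression gate (deviance decrease plus likelihood-ratio
# significance) on the strong/weak sequence sets. Finished motifs are masked
# out of all sequences and the next PWM is seeded from the remaining words.
#
# The PWM is accumulated in "loading space": each matched cell carries the sum
# of the loadings of the words aligned over it, and the probability view
# renormalizes every motif position to one.

#' Construct a PWM motif object
#'
#' @param columns Numeric L x 4 matrix, one row per motif position with
#'   A,C,G,T weights; rows are renormalized to sum to one.
#' @param source_words Optional tibble of `word`, `loading` consumed by the
#'   motif.
#' @return A `pwm_motif` with fields `columns` (probabilities), `weights`
#'   (raw loading sums), `source_words`, `cutoff` (unset until calibrated) and
#'   `fit_stat`.
#' @export
pwm_motif <- function(columns, source_words = tibble(word = character(),
                                                     loading = numeric())) {
  columns <- as.matrix(columns)
  if (ncol(columns) != 4L) abort("PWM needs 4 base columns (A,C,G,T)",
                                 class = "mslseq_input_error")
  if (any(columns < 0) || any(rowSums(columns) <= 0)) {
    abort("PWM weights must be non-negative with positive position sums",
          class = "mslseq_input_error")
  }
  colnames(columns) <- BASES
  new_pwm(columns, source_words)
}

new_pwm <- function(weights, source_words, fit_stat = NA_real_, cutoff = NULL) {
  structure(
    list(columns = weights / rowSums(weights), weights = weights,
         source_words = source_words, cutoff = cutoff, fit_stat = fit_stat),
    class = "pwm_motif"
  )
}

pwm_from_word <- function(word, loading) {
  letters <- match(strsplit(toupper(word), "", fixed = TRUE)[[1L]], BASES)
  if (anyNA(letters)) abort("seed word must be over ACGT", class = "mslseq_input_error")
  w <- matrix(0, length(letters), 4L, dimnames = list(NULL, BASES))
  w[cbind(seq_along(letters), letters)] <- loading
  new_pwm(w, tibble(word = word, loading = loading))
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif> %d positions, %d source word(s), consensus %s%s\n",
              nrow(x$columns), nrow(x$source_words), pwm_consensus(x),
              if (is.null(x$cutoff)) "" else sprintf(", cutoff %.3g", x$cutoff)))
  invisible(x)
}

#' @rdname pwm_motif
#' @param x A `pwm_motif`.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$columns, 1L, which.max)], collapse = "")
}

#' Information content of a PWM
#'
#' @param x A `pwm_motif`.
#' @return Total information content in bits (sum over positions of
#'   2 + sum p log2 p).
#' @export
pwm_information <- function(x) {
  p <- x$columns
  sum(2 + rowSums(ifelse(p > 0, p * log2(p), 0)))
}

# reverse-complement a position-probability (or weight) matrix
rc_mat <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- BASES
  out
}

# per-position scores of a PWM over an integer sequence matrix, both strands;
# returns n x (maxlen - L + 1) matrix (positions running off a shorter
# sequence's end score 0 through the N padding)
position_scores <- function(columns, S) {
  L <- nrow(columns)
  W <- ncol(S) - L + 1L
  if (W < 1L) abort("sequence shorter than the PWM", class = "mslseq_input_error")
  one_strand <- function(cols) {
    P <- matrix(1, nrow(S), W)
    for (i in seq_len(L)) {
      probs <- c(0, cols[i, ])   # leading 0 scores N and padding
      P <- P * matrix(probs[S[, i:(i + W - 1L), drop = FALSE] + 1L], nrow(S), W)
    }
    P
  }
  pmax(one_strand(columns), one_strand(rc_mat(columns)))
}

# summed top-n per-position scores for a character vector of sequences
scan_scores <- function(pwm, seqs, top_n = 1L) {
  L <- nrow(pwm$columns)
  if (any(nchar(seqs) < L)) {
    abort("all sequences must be at least as long as the PWM",
          class = "mslseq_input_error")
  }
  P <- position_scores(pwm$columns, seqs_to_intmat(seqs))
  if (top_n == 1L) return(apply(P, 1L, max))
  apply(P, 1L, function(v) sum(sort(v, decreasing = TRUE)[seq_len(min(top_n, length(v)))]))
}

#' Score a PWM against one sequence
#'
#' The motif is scored at every position by multiplying the PWM values of the
#' matching bases (an N contributes zero); both strands are scanned and the
#' better strand taken per position; the `top_n` largest per-position scores
#' are summed.
#'
#' @param pwm A `pwm_motif`.
#' @param sequence A DNA string at least as long as the PWM.
#' @param top_n Number of best per-position scores to sum (default 1).
#' @return The summed score.
#' @export
score_pwm <- function(pwm, sequence, top_n = 1) {
  stopifnot(inherits(pwm, "pwm_motif"), is.character(sequence),
            length(sequence) == 1L)
  scan_scores(pwm, sequence, as.integer(top_n))
}

#' Aligner parameters
#'
#' @param top_n_words Number of top-loaded words fed to the aligner.
#' @param best_scores_per_seq How many best per-sequence scores are summed
#'   when scoring (and how many occurrences are masked).
#' @param min_overlap Minimum overlapping motif positions for an admissible
#'   alignment offset; default `ceiling(word length / 2)` per word.
#' @param max_motifs Maximum number of motifs built before stopping.
#' @param improvement_alpha Significance level of the likelihood-ratio gate.
#' @param target_fpr Calibrated false-positive fraction on the negative set.
#' @param gate_pool Number of top-compatibility candidates whose logistic gate
#'   is evaluated per iteration (all unconsumed words are ranked each
#'   iteration; the gate runs on the best `gate_pool`).
#' @param min_loading_frac Stop seeding once the top unconsumed loading falls
#'   below this fraction of the maximum loading.
#' @param max_extensions Hard cap on accepted extensions per motif.
#' @return A list of class `aligner_params`.
#' @export
aligner_params <- function(top_n_words = 1000, best_scores_per_seq = 1,
                           min_overlap = NULL, max_motifs = 5,
                           improvement_alpha = 0.05, target_fpr = 0.05,
                           gate_pool = 50, min_loading_frac = 0.1,
                           max_extensions = 40) {
  stopifnot(top_n_words >= 1, best_scores_per_seq >= 1, max_motifs >= 1,
            improvement_alpha > 0, improvement_alpha < 1,
            target_fpr > 0, target_fpr < 1, gate_pool >= 1,
            max_extensions >= 1)
  structure(list(top_n_words = top_n_words,
                 best_scores_per_seq = as.integer(best_scores_per_seq),
                 min_overlap = min_overlap, max_motifs = max_motifs,
                 improvement_alpha = improvement_alpha,
                 target_fpr = target_fpr, gate_pool = gate_pool,
                 min_loading_frac = min_loading_frac,
                 max_extensions = as.integer(max_extensions)),
            class = "aligner_params")
}

#' Candidate extensions of a PWM by one word
#'
#' Tests the word and its reverse complement at every offset sharing at least
#' `min_overlap` positions with the PWM (overhangs extend the motif); each
#' candidate adds the word's loading to the matching base cell of every
#' aligned position and renormalizes. The two most compatible distinct offsets
#' are additionally combined into one simultaneous-alignment candidate.
#'
#' @param pwm Current `pwm_motif`.
#' @param word Extension word (2-6 bp).
#' @param loading Positive loading weight of the word.
#' @param params An [aligner_params()] list.
#' @return List of candidate `pwm_motif`s, ranked by alignment compatibility
#'   (the pre-normalization dot product of the word with the overlapped PWM
#'   positions), each carrying attributes `compat`, `offset`, `orient`.
#' @export
align_word <- function(pwm, word, loading, params = aligner_params()) {
  recs <- enumerate_offsets(pwm, word, loading, params)
  if (!length(recs)) return(list())
  out <- lapply(recs, function(cd)
    build_extension(pwm, word, loading, list(cd), cd$compat))
  # one simultaneous double alignment: the best two distinct offsets
  dbl <- double_record(recs)
  if (!is.null(dbl)) {
    out <- append(out, list(
      build_extension(pwm, word, loading, dbl$exts, dbl$compat)))
  }
  out[order(vapply(out, attr, 0, "compat"), decreasing = TRUE)]
}

# admissible alignment records of a word against a PWM, ranked by
# compatibility; cheap (no candidate matrices are built)
enumerate_offsets <- function(pwm, word, loading, params) {
  if (!is.numeric(loading) || loading <= 0) {
    abort("`loading` must be positive", class = "mslseq_parameter_error")
  }
  m <- nchar(word)
  stopifnot(m >= 2, m <= 6)
  min_ov <- params$min_overlap %||% ceiling(m / 2)
  L <- nrow(pwm$weights)
  orients <- unique(c(word, revcomp(word)))
  cands <- list()
  for (orient in seq_along(orients)) {
    letters <- match(strsplit(orients[[orient]], "", fixed = TRUE)[[1L]], BASES)
    for (s in seq(-(m - 1L), L - 1L)) {
      overlap <- min(L, s + m) - max(0L, s)
      if (overlap < min_ov) next
      inside <- which(s + seq_len(m) - 1L >= 0L & s + seq_len(m) - 1L <= L - 1L)
      compat <- sum(pwm$columns[cbind(s + inside, letters[inside])])
      cands[[length(cands) + 1L]] <-
        list(s = s, letters = letters, compat = compat,
             orient = if (orient == 1L) "+" else "-")
    }
  }
  if (!length(cands)) return(list())
  cands[order(vapply(cands, `[[`, 0, "compat"), decreasing = TRUE)]
}

# best double alignment: the top record plus the best at a distinct offset
double_record <- function(recs) {
  if (length(recs) < 2L) return(NULL)
  first <- recs[[1L]]
  distinct <- which(vapply(recs, `[[`, 0L, "s") != first$s |
                    vapply(recs, `[[`, "", "orient") != first$orient)
  if (!length(distinct)) return(NULL)
  second <- recs[[distinct[1L]]]
  list(exts = list(first, second), compat = first$compat + second$compat)
}

# realize a candidate PWM from alignment records
build_extension <- function(pwm, word, loading, extensions, compat) {
  L <- nrow(pwm$weights)
  lo <- min(0L, vapply(extensions, `[[`, 0L, "s"))
  hi <- max(L, vapply(extensions, function(e) e$s + length(e$letters), 0L))
  W2 <- matrix(0, hi - lo, 4L, dimnames = list(NULL, BASES))
  W2[(1L - lo):(L - lo), ] <- pwm$weights
  for (e in extensions) {
    idx <- cbind(e$s - lo + seq_along(e$letters), e$letters)
    W2[idx] <- W2[idx] + loading
  }
  out <- new_pwm(W2, bind_rows(pwm$source_words,
                               tibble(word = word, loading = loading)))
  out$fit_stat <- NA_real_
  attr(out, "compat") <- compat
  attr(out, "offset") <- vapply(extensions, `[[`, 0L, "s")
  attr(out, "orient") <- vapply(extensions, `[[`, "", "orient")
  out
}

#' Logistic-regression gate for a PWM update
#'
#' Each candidate PWM is scored over the positive and negative sequence sets;
#' the candidate is accepted if its logistic model (class ~ score) improves
#' the current PWM's deviance by at least the chi-square(1) quantile at
#' `improvement_alpha` (a significant predictive improvement, not merely a
#' numerically lower deviance) and the score is significant against the
#' intercept-only model by a likelihood-ratio test at `improvement_alpha`.
#' Pass `old_pwm = NULL` to gate a freshly seeded PWM (intercept-only
#' comparison).
#'
#' @param old_pwm Current `pwm_motif` or `NULL`.
#' @param new_pwm Candidate `pwm_motif`.
#' @param pos_seqs,neg_seqs Character vectors of positive/negative sequences.
#' @param params An [aligner_params()] list.
#' @param old_dev Optional known deviance of `old_pwm` (skips rescoring it).
#' @return List with `accepted`, `fit_stat` (candidate deviance) and
#'   `p_value` of the likelihood-ratio test.
#' @export
accept_extension <- function(old_pwm, new_pwm, pos_seqs, neg_seqs,
                             params = aligner_params(), old_dev = NULL) {
  if (!length(pos_seqs) || !length(neg_seqs)) {
    abort("both sequence sets must be non-empty", class = "mslseq_input_error")
  }
  y <- c(rep(1L, length(pos_seqs)), rep(0L, length(neg_seqs)))
  seqs <- c(pos_seqs, neg_seqs)
  dev_of <- function(pwm) {
    sc <- scan_scores(pwm, seqs, params$best_scores_per_seq)
    if (sd(sc) == 0) return(NULL)
    z <- (sc - mean(sc)) / sd(sc)
    fit <- suppressWarnings(glm(y ~ z, family = binomial()))
    list(dev = fit$deviance,
         p = pchisq(fit$null.deviance - fit$deviance, df = 1L,
                    lower.tail = FALSE))
  }
  new_fit <- dev_of(new_pwm)
  if (is.null(new_fit)) {
    return(list(accepted = FALSE, fit_stat = NA_real_, p_value = NA_real_))
  }
  ok <- new_fit$p < params$improvement_alpha
  if (!is.null(old_pwm) || !is.null(old_dev)) {
    if (is.null(old_dev)) {
      old_fit <- dev_of(old_pwm)
      old_dev <- if (is.null(old_fit)) Inf else old_fit$dev
    }
    min_drop <- stats::qchisq(1 - params$improvement_alpha, df = 1L)
    ok <- ok && (new_fit$dev <= old_dev - min_drop)
  }
  list(accepted = isTRUE(ok), fit_stat = new_fit$dev, p_value = new_fit$p)
}

#' Score cutoff at a target false-positive rate
#'
#' @param scores Best score per negative sequence.
#' @param target_fpr Maximum fraction of negatives allowed at/above cutoff.
#' @return The smallest observed score such that
#'   `mean(scores >= cutoff) <= target_fpr`; just above the maximum when even
#'   the maximum is too frequent (presence fraction then 0).
#' @export
cutoff_from_scores <- function(scores, target_fpr = 0.05) {
  stopifnot(length(scores) > 0)
  vals <- sort(unique(scores), decreasing = TRUE)
  fr <- vapply(vals, function(v) mean(scores >= v), 0)
  ok <- which(fr <= target_fpr)
  if (!length(ok)) {
    mx <- max(scores)
    return(mx + max(1e-12, abs(mx) * 1e-9))
  }
  vals[max(ok)]
}

#' Calibrate a motif's presence cutoff on negative promoters
#'
#' Uses the best score of the motif in each negative sequence and picks the
#' cutoff so the motif is called present in at most `target_fpr` of them.
#'
#' @param pwm A `pwm_motif`.
#' @param neg_seqs Character vector of negative (weakly bound) promoters.
#' @param target_fpr Target false-positive fraction (default 0.05).
#' @return The `pwm_motif` with `cutoff` set.
#' @export
calibrate_cutoff <- function(pwm, neg_seqs, target_fpr = 0.05) {
  if (!length(neg_seqs)) abort("negative set is empty", class = "mslseq_input_error")
  pwm$cutoff <- cutoff_from_scores(scan_scores(pwm, neg_seqs, 1L), target_fpr)
  pwm
}

#' Fraction of sequences carrying a motif
#'
#' @param pwm A calibrated `pwm_motif` (cutoff set).
#' @param seqs Character vector of sequences, oriented 5' to 3' toward the TSS
#'   (the TSS-proximal end is the 3' end).
#' @param window Restrict scanning to the `window` TSS-proximal bases
#'   (default: whole sequence).
#' @return Fraction of sequences whose best score reaches the cutoff;
#'   `NA` (with a warning) for an empty set.
#' @export
motif_presence_fraction <- function(pwm, seqs, window = NULL) {
  if (is.null(pwm$cutoff)) {
    abort("cutoff not set; run calibrate_cutoff() first", class = "mslseq_state_error")
  }
  if (!length(seqs)) {
    warn("empty sequence set; presence fraction undefined")
    return(NA_real_)
  }
  if (!is.null(window)) {
    n <- nchar(seqs)
    seqs <- substr(seqs, pmax(1L, n - as.integer(window) + 1L), n)
  }
  mean(scan_scores(pwm, seqs, 1L) >= pwm$cutoff)
}

# replace the best above-cutoff occurrence(s) of a motif with Ns
mask_motif <- function(seqs, pwm, cutoff, n_best = 1L) {
  L <- nrow(pwm$columns)
  P <- position_scores(pwm$columns, seqs_to_intmat(seqs))
  for (i in seq_along(seqs)) {
    v <- P[i, ]
    for (b in seq_len(n_best)) {
      j <- which.max(v)
      if (v[j] < cutoff || v[j] <= 0) break
      substr(seqs[i], j, j + L - 1L) <- strrep("N", L)
      lo <- max(1L, j - L + 1L)
      v[lo:min(length(v), j + L - 1L)] <- -Inf
    }
  }
  seqs
}

#' Build motifs from discriminative words
#'
#' The iterative aligner: seeds a PWM from the top unconsumed
#' word (words failing the seed gate are skipped), repeatedly extends it with
#' the best gate-passing candidate word (both orientations, all admissible
#' offsets, single or double alignment), and on stagnation calibrates the
#' motif's cutoff, masks its occurrences in all sequences, and seeds the next
#' motif. Words consumed by one motif are never reused.
#'
#' @param words Tibble/data frame with `word` and `loading` (positive,
#'   sorted descending; unsorted input is sorted), or a named numeric vector.
#' @param pos_seqs,neg_seqs Positive (strong) and negative (weak) sequences.
#' @param params An [aligner_params()] list.
#' @param verbose Print progress.
#' @return List of calibrated `pwm_motif`s (possibly empty).
#' @export
build_motifs <- function(words, pos_seqs, neg_seqs, params = aligner_params(),
                         verbose = FALSE) {
  if (is.numeric(words)) words <- tibble(word = names(words), loading = unname(words))
  words <- as_tibble(words)
  stopifnot(all(c("word", "loading") %in% names(words)))
  words <- words |>
    filter(.data$loading > 0, !duplicated(.data$word)) |>
    arrange(desc(.data$loading)) |>
    slice_head(n = params$top_n_words)
  if (!nrow(words)) abort("no usable words", class = "mslseq_input_error")
  max_loading <- words$loading[1L]
  consumed <- rep(FALSE, nrow(words))
  pos <- pos_seqs; neg <- neg_seqs
  motifs <- list()
  while (length(motifs) < params$max_motifs) {
    avail <- which(!consumed & words$loading >= params$min_loading_frac * max_loading)
    if (!length(avail)) break
    # seed: first of the top gate_pool unconsumed words that gates in
    pwm <- NULL
    for (i in head(avail, params$gate_pool)) {
      cand <- pwm_from_word(words$word[i], words$loading[i])
      res <- accept_extension(NULL, cand, pos, neg, params)
      if (res$accepted) {
        pwm <- cand; pwm$fit_stat <- res$fit_stat
        consumed[i] <- TRUE
        if (verbose) message("seed: ", words$word[i])
        break
      }
    }
    if (is.null(pwm)) break
    # extension loop
    n_ext <- 0L
    repeat {
      avail <- which(!consumed)
      if (!length(avail) || n_ext >= params$max_extensions) break
      # rank every unconsumed word's best single and double alignment by
      # compatibility; realize and gate only the top of the pool
      cands <- list()
      for (i in avail) {
        recs <- enumerate_offsets(pwm, words$word[i], words$loading[i], params)
        if (!length(recs)) next
        cands[[length(cands) + 1L]] <-
          list(word_idx = i, exts = recs[1L], compat = recs[[1L]]$compat)
        dbl <- double_record(recs)
        if (!is.null(dbl)) {
          cands[[length(cands) + 1L]] <-
            list(word_idx = i, exts = dbl$exts, compat = dbl$compat)
        }
      }
      if (!length(cands)) break
      ord <- order(vapply(cands, `[[`, 0, "compat"), decreasing = TRUE)
      cands <- cands[head(ord, params$gate_pool)]
      best <- NULL; best_dev <- Inf
      for (cd in cands) {
        cand_pwm <- build_extension(pwm, words$word[cd$word_idx],
                                    words$loading[cd$word_idx], cd$exts,
                                    cd$compat)
        res <- accept_extension(NULL, cand_pwm, pos, neg, params,
                                old_dev = pwm$fit_stat)
        if (res$accepted && res$fit_stat < best_dev) {
          best <- cand_pwm; best$fit_stat <- res$fit_stat
          best_dev <- res$fit_stat
          attr(best, "word_idx") <- cd$word_idx
        }
      }
      if (is.null(best)) break
      n_ext <- n_ext + 1L
      consumed[attr(best, "word_idx")] <- TRUE
      if (verbose) message("  + ", tail(best$source_words$word, 1L),
                           " (dev ", signif(best_dev, 4L), ")")
      pwm <- best
    }
    pwm <- calibrate_cutoff(pwm, neg, params$target_fpr)
    pos <- mask_motif(pos, pwm, pwm$cutoff, params$best_scores_per_seq)
    neg <- mask_motif(neg, pwm, pwm$cutoff, params$best_scores_per_seq)
    motifs[[length(motifs) + 1L]] <- pwm
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param pwms A `pwm_motif` or list of them.
#' @param path Output file.
#' @param background Background base probabilities (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  if (inherits(pwms, "pwm_motif")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", BASES, background), collapse = " "),
               ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]$columns
    writeLines(c(sprintf("MOTIF motif_%d %s", i, pwm_consensus(pwms[[i]])),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(p), max(1L, nrow(pwms[[i]]$source_words)))), con)
    writeLines(apply(p, 1L, function(r) paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Long-format view of a PWM
#'
#' @param x A `pwm_motif`.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `prob`, `weight`.
#' @export
tidy.pwm_motif <- function(x, ...) {
  tibble(
    position = rep(seq_len(nrow(x$columns)), times = 4L),
    base = rep(BASES, each = nrow(x$columns)),
    prob = as.vector(x$columns),
    weight = as.vector(x$weights)
  )
}
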