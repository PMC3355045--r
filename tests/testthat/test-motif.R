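one_hot_pwm <- function(word) {
  m <- diag(4)[match(strsplit(word, "")[[1]], c("A", "C", "G", "T")), ]
  colnames(m) <- c("A", "C", "G", "T")
  pwm_motif(m)
}

test_that("PWM scoring multiplies matching positions and scans both strands", {
  ac <- one_hot_pwm("AC")
  expect_equal(score_pwm(ac, "GACG", top_n = 1), 1)     # one exact site
  expect_equal(score_pwm(ac, "ACAC", top_n = 2), 2)     # two sites summed
  expect_equal(score_pwm(ac, "GGTG", top_n = 1), 1)     # GT on the other strand
  uni <- pwm_motif(matrix(0.25, 3, 4))
  expect_equal(score_pwm(uni, strrep("A", 10)), 0.25^3)
  expect_error(score_pwm(one_hot_pwm("ACGT"), "AC"),
               class = "mslseq_input_error")
  # N contributes zero
  expect_equal(score_pwm(ac, "ANC"), 0)
})

test_that("alignment candidates renormalize and extend correctly", {
  params <- aligner_params()
  gatc <- one_hot_pwm("GATC")
  # same word at offset 0: renormalization is idempotent
  cands <- align_word(gatc, "GATC", 1, params)
  best <- cands[[1]]
  expect_equal(attr(best, "offset"), 0L)
  expect_equal(best$columns, gatc$columns, ignore_attr = TRUE)
  # offset +1 extension grows the PWM to 5 columns
  cands <- align_word(gatc, "ATCA", 1, params)
  off1 <- Filter(function(cd) identical(attr(cd, "offset"), 1L) &&
                   identical(attr(cd, "orient"), "+"), cands)[[1]]
  expect_equal(nrow(off1$columns), 5L)
  expect_equal(unname(off1$columns[1, "G"]), 1)   # seed-only column
  expect_equal(unname(off1$columns[5, "A"]), 1)   # overhang column
  expect_equal(unname(off1$columns[2, "A"]), 1)   # agreeing interior columns
  expect_equal(rowSums(off1$columns), rep(1, 5), ignore_attr = TRUE)
  expect_error(align_word(gatc, "ATCA", -1), class = "mslseq_parameter_error")
})

test_that("the best orientation/offset agrees with exhaustive enumeration", {
  pwm <- one_hot_pwm("GATC")
  word <- "CTAG"   # self-complementary: one orientation to test
  cands <- align_word(pwm, word, 1, aligner_params())
  # single alignments only (the double-alignment candidate pools two offsets)
  cands <- Filter(function(cd) length(attr(cd, "offset")) == 1L, cands)
  # brute force: score every orientation x offset by summed matching columns
  brute <- list()
  for (w in unique(c(word, revcomp(word)))) {
    l <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    for (s in -3:3) {
      inside <- which(s + seq_len(4) - 1 >= 0 & s + seq_len(4) - 1 <= 3)
      if (length(inside) < 2) next
      brute[[length(brute) + 1]] <-
        list(compat = sum(pwm$columns[cbind(s + inside, l[inside])]))
    }
  }
  expect_equal(attr(cands[[1]], "compat"), max(vapply(brute, `[[`, 0, "compat")))
})

test_that("the logistic gate rejects null or unchanged updates", {
  params <- aligner_params()
  withr::with_seed(5, {
    pos <- planted_promoters(40, 1, one_hot_pwm("GATCGATC")$columns, len = 120)
    neg <- planted_promoters(40, 0, one_hot_pwm("GATCGATC")$columns, len = 120)
  })
  pwm <- one_hot_pwm("GATCGATC")
  res <- accept_extension(NULL, pwm, pos, neg, params)
  expect_true(res$accepted)   # the true motif separates the sets
  # new == old: no deviance improvement
  expect_false(accept_extension(pwm, pwm, pos, neg, params)$accepted)
  # identical positive and negative sets carry no signal
  expect_false(accept_extension(NULL, pwm, pos, pos, params)$accepted)
  # degenerate (constant) scores are rejected, not an error
  res0 <- accept_extension(NULL, one_hot_pwm("AAAA"),
                           c("CCCC", "CCCC"), c("CCCC", "CCCC"), params)
  expect_false(res0$accepted)
})

test_that("cutoffs follow the order statistic at the target FPR", {
  expect_equal(cutoff_from_scores(1:100, 0.05), 96)
  expect_equal(cutoff_from_scores(1:200, 0.05), 191)
  # all scores equal: cutoff sits above, presence is zero
  cut <- cutoff_from_scores(rep(2, 50), 0.05)
  expect_gt(cut, 2)
  expect_equal(mean(rep(2, 50) >= cut), 0)
})

test_that("presence fractions respect calibration and flag degenerate input", {
  pwm <- default_planted_pwm()
  consensus <- one_hot_pwm(paste(c("A", "C", "G", "T")[apply(pwm, 1, which.max)],
                                 collapse = ""))
  withr::with_seed(21, {
    strong <- planted_promoters(120, 1, consensus$columns)  # consensus inserts
    weak <- planted_promoters(150, 0, consensus$columns)
    held_weak <- planted_promoters(200, 0, consensus$columns)
  })
  cal <- calibrate_cutoff(consensus, weak, 0.05)
  expect_lte(motif_presence_fraction(cal, weak, 500), 0.05)   # by construction
  expect_lte(motif_presence_fraction(cal, held_weak, 500), 0.07)
  expect_gte(motif_presence_fraction(cal, strong, 500), 0.95)
  expect_error(motif_presence_fraction(consensus, strong),
               class = "mslseq_state_error")
  expect_warning(out <- motif_presence_fraction(cal, character(0)),
                 "empty")
  expect_true(is.na(out))
})

test_that("a lone discriminative word seeds a one-word motif", {
  withr::with_seed(33, {
    pos <- planted_promoters(40, 1, one_hot_pwm("GACGTC")$columns, len = 150)
    neg <- planted_promoters(40, 0, one_hot_pwm("GACGTC")$columns, len = 150)
  })
  motifs <- build_motifs(tibble::tibble(word = "GACGTC", loading = 1),
                         pos, neg, aligner_params(max_motifs = 2))
  expect_length(motifs, 1L)
  expect_equal(pwm_consensus(motifs[[1]]), "GACGTC")
  expect_equal(unname(apply(motifs[[1]]$columns, 1, max)), rep(1, 6))
  expect_error(build_motifs(tibble::tibble(word = character(),
                                           loading = numeric()),
                            pos, neg),
               class = "mslseq_input_error")
})

test_that("motif construction keeps invariants: columns, words, masking", {
  withr::with_seed(44, {
    pos <- planted_promoters(60, 0.9, default_planted_pwm(), len = 300)
    neg <- planted_promoters(60, 0.05, default_planted_pwm(), len = 300)
  })
  words <- tibble::tibble(
    word = c("TATCGA", "ATCGAT", "TCGATA", "CGATAG", "GATAGA", "GGCCTT"),
    loading = c(6, 5, 4, 3, 2, 1))
  motifs <- build_motifs(words, pos, neg,
                         aligner_params(max_motifs = 2, gate_pool = 10))
  expect_gte(length(motifs), 1L)
  src <- unlist(lapply(motifs, function(m) m$source_words$word))
  expect_false(any(duplicated(src)))   # a word is consumed at most once
  for (m in motifs) {
    expect_equal(rowSums(m$columns), rep(1, nrow(m$columns)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_false(is.null(m$cutoff))
  }
  # masking never raises a sequence's best score
  m1 <- motifs[[1]]
  before <- vapply(pos, function(s) score_pwm(m1, s), 0)
  masked <- mslseq:::mask_motif(pos, m1, m1$cutoff)
  after <- vapply(masked, function(s) score_pwm(m1, s), 0)
  expect_true(all(after <= before + 1e-12))
})

test_that("motifs export in MEME minimal format", {
  m <- one_hot_pwm("GATC")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(m), path)
  txt <- readLines(path)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("^MOTIF motif_1 GATC", txt)))
  expect_equal(sum(grepl("^letter-probability", txt)), 1L)
  td <- tidy(m)
  expect_equal(nrow(td), 16L)
  expect_equal(sum(td$prob), 4)
})
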