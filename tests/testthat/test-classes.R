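mk_binding <- function(gene_id, v1, v2, v3) {
  tibble::tibble(gene_id = rep(gene_id, 3),
                 protein = c("MSL1", "MSL3", "MOF"),
                 binding_value = c(v1, v2, v3))
}

test_that("gene classes follow the binding and expression thresholds", {
  binding <- dplyr::bind_rows(
    mk_binding("g1", 1.2, 1.1, 1.3),
    mk_binding("g2", 0.2, 0.3, 0.4),
    mk_binding("g3", 0.7, 1.2, 1.3),
    mk_binding("g4", 1.5, 1.5, 1.5),
    mk_binding("g5", 1.5, 1.5, 1.5))
  expression <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    rep1 = c(7, 8, 7, 5, 11), rep2 = c(7.1, 8, 7, 5, 11),
    rep3 = c(6.9, 8, 7, 5, 11))
  ct <- classify_genes(binding, expression)
  expect_equal(ct$class[match(paste0("g", 1:5), ct$gene_id)],
               c("strong_expressed", "weak_expressed", "intermediate",
                 "unexpressed", "excluded_high_expression"))
  expect_equal(ct$expression[ct$gene_id == "g1"], 7)  # median of replicates
  expect_equal(ct$avg_msl[ct$gene_id == "g1"], mean(c(1.2, 1.1, 1.3)))
  # every gene lands in exactly one class
  expect_equal(nrow(ct), 5L)
  expect_error(classify_genes(binding[binding$protein != "MOF", ], expression),
               class = "mslseq_schema_error")
})

test_that("CDS thirds split 5'-heavy and exclude short sequences", {
  p <- split_cds_thirds(strrep("ACT", 3), min_len = 9)
  expect_equal(nchar(unlist(p)), c(3, 3, 3), ignore_attr = TRUE)
  p10 <- split_cds_thirds(paste(rep("A", 10), collapse = ""), min_len = 9)
  expect_equal(nchar(unlist(p10)), c(4, 3, 3), ignore_attr = TRUE)
  expect_warning(out <- split_cds_thirds(strrep("A", 17)), "excluded")
  expect_null(out)
  # concatenating the thirds reconstructs the CDS exactly
  s <- rand_seq(100)
  expect_equal(paste(unlist(split_cds_thirds(s)), collapse = ""), s)
})

test_that("strand/frame counting variants differ as specified", {
  v_frame <- strand_frame_variants("ATGATG", 3, "in_frame_only")
  expect_equal(unname(v_frame["ATG"]), 2 / 6)
  expect_length(v_frame, 1L)
  v_tx <- strand_frame_variants("ATGATG", 3, "transcribed_only")
  expect_equal(unname(v_tx["ATG"]), 2 / 6)
  expect_false("CAT" %in% names(v_tx))   # no reverse-complement merging
  # both_strands equals the merged counter
  s <- rand_seq(300)
  v_both <- strand_frame_variants(s, 3, "both_strands")
  ref <- count_words(s, 3) / nchar(s)
  expect_equal(v_both[order(names(v_both))], ref[order(names(ref))])
  expect_warning(strand_frame_variants("ATGAT", 3, "in_frame_only"),
                 "truncating")
})

test_that("codon usage comparison behaves under null, self and shift", {
  withr::with_seed(61, {
    all_codons <- apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1, paste,
                        collapse = "")
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(all_codons, stops)
    # biased set: half the draws switch to an A/T-ending synonym
    at_synonym <- vapply(sense, function(cd) {
      fam <- sense[Biostrings::GENETIC_CODE[sense] ==
                     Biostrings::GENETIC_CODE[cd]]
      at <- fam[substr(fam, 3, 3) %in% c("A", "T")]
      if (length(at)) at[1] else cd
    }, "")
    mk_cds <- function(n, bias = FALSE) {
      vapply(seq_len(n), function(i) {
        codons <- sample(sense, 200, replace = TRUE)
        if (bias) {
          sw <- runif(200) < 0.5
          codons[sw] <- at_synonym[codons[sw]]
        }
        paste(codons, collapse = "")
      }, "")
    }
    a <- mk_cds(40); b <- mk_cds(40); c_bias <- mk_cds(40, bias = TRUE)
  })
  self <- codon_usage_compare(a, a)
  expect_true(self$test$degenerate_test)
  expect_true(all(self$usage$rscu_a == self$usage$rscu_b, na.rm = TRUE))
  null <- codon_usage_compare(a, b)
  expect_equal(null$test$n_codons, 59L)
  expect_gt(null$test$p_value, 0.05)
  shift <- codon_usage_compare(a, c_bias)
  expect_lt(shift$test$p_value, 0.01)
  expect_error(codon_usage_compare(character(), b),
               class = "mslseq_input_error")
})

test_that("RSCU agrees with the seqinr reference on a fixture", {
  skip_if_not_installed("seqinr")
  withr::with_seed(77, s <- paste(sample(c("A", "C", "G", "T"), 3 * 500,
                                         replace = TRUE), collapse = ""))
  ours <- mslseq:::rscu_table(s)
  ref <- seqinr::uco(strsplit(tolower(s), "")[[1]], index = "rscu")
  m <- match(tolower(ours$codon), names(ref))
  ok <- is.finite(ours$rscu)
  expect_equal(ours$rscu[ok], unname(ref[m])[ok], tolerance = 1e-10)
})

test_that("group comparisons wrap the standard tests", {
  withr::with_seed(3, {
    a <- rnorm(50); b <- rnorm(50) + 5
  })
  res <- compare_groups(a, b, "mann_whitney")
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$n_a, 50L)
  x <- 1:20
  rho <- compare_groups(x, exp(x / 3), "spearman")
  expect_equal(unname(rho$statistic), 0)   # S = 0 at rho = 1
  expect_error(compare_groups(1:5, 1:4, "paired_t"),
               class = "mslseq_input_error")
  same <- compare_groups(a, a + rnorm(50, 0, 1e-8), "mann_whitney")
  expect_gt(same$p_value, 0.3)
})

test_that("thirds bias scoring flags single-gene input", {
  withr::with_seed(9, {
    dat <- synth_word_enriched_seqs(40, len = 300, seed = 5)
  })
  wm <- scale_matrix(word_matrix(setNames(dat$bases, dat$obs_id), 2, 4,
                                 "canonical"), "uv_scaled")
  fit <- fit_oplsda(wm, dat$class, n_orth = 0, folds = 4, seed = 1,
                    positive = "enriched")
  one <- thirds_bias_test(fit, tibble::tibble(gene_id = "g1",
                                              bases = rand_seq(120)),
                          2, 4, "canonical")
  expect_true(one$test$insufficient_n)
  expect_equal(nrow(one$scores), 1L)
  expect_true(all(is.finite(unlist(one$scores[, -1]))))
})
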