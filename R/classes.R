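# Gene classification from binding and expression, CDS thirds, strand/frame
# counting variants, codon-usage comparison, and the standard group tests.

#' Classify genes by MSL binding and expression
#'
#' Expression is the median over replicates. Genes below the low expression
#' bound are `unexpressed`; above the high bound `excluded_high_expression`
#' (expressed, but their response cannot be estimated accurately). Expressed
#' genes with all three protein binding values above `strong_cut` (log2) are
#' `strong_expressed`; all three below `weak_cut` are `weak_expressed`;
#' anything else is `intermediate` (excluded from model sets).
#'
#' @param binding Tibble `gene_id`, `protein`, `binding_value` (long; exactly
#'   three proteins per gene).
#' @param expression Tibble with `gene_id` and one column per replicate.
#' @param strong_cut,weak_cut Binding thresholds (defaults 1.0, 0.5, log2).
#' @param expr_window Expressed window (default `c(6, 10)`).
#' @return Tibble: `gene_id`, `expression`, one `binding_<protein>` column per
#'   protein, `avg_msl` (mean of the three binding values) and `class`.
#' @export
classify_genes <- function(binding, expression, strong_cut = 1.0,
                           weak_cut = 0.5, expr_window = c(6, 10)) {
  stopifnot(all(c("gene_id", "protein", "binding_value") %in% names(binding)))
  proteins <- sort(unique(binding$protein))
  if (length(proteins) != 3L) {
    abort("three binding proteins are required", class = "mslseq_schema_error")
  }
  wide <- binding |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "protein",
                       values_from = "binding_value", names_prefix = "binding_")
  bcols <- paste0("binding_", proteins)
  if (!all(bcols %in% names(wide))) {
    abort("missing protein column", class = "mslseq_schema_error")
  }
  reps <- expression[setdiff(names(expression), "gene_id")]
  if (!ncol(reps)) abort("expression needs at least one replicate column",
                         class = "mslseq_schema_error")
  med <- apply(as.matrix(reps), 1L, median, na.rm = TRUE)
  tbl <- tibble(gene_id = expression$gene_id, expression = med) |>
    inner_join(wide, by = "gene_id")
  bm <- as.matrix(tbl[bcols])
  tbl |>
    mutate(
      avg_msl = rowMeans(bm),
      class = dplyr::case_when(
        .data$expression < expr_window[1L] ~ "unexpressed",
        .data$expression > expr_window[2L] ~ "excluded_high_expression",
        rowSums(bm > strong_cut) == 3L ~ "strong_expressed",
        rowSums(bm < weak_cut) == 3L ~ "weak_expressed",
        TRUE ~ "intermediate"
      )
    )
}

#' Split a CDS into three equally sized parts
#'
#' Parts are ordered in the direction of transcription; when the length is
#' not divisible by three the remainder bases go to the 5'-most parts, so the
#' 3' third is never the longest.
#'
#' @param cds CDS string on the coding strand.
#' @param min_len Minimum usable CDS length (default 18 = 3 x longest word).
#' @return Named list `five_prime`, `middle`, `three_prime`, or `NULL` (with
#'   a warning) for a too-short CDS.
#' @export
split_cds_thirds <- function(cds, min_len = 18) {
  n <- nchar(cds)
  if (n < min_len) {
    warn(sprintf("CDS of length %d below %d; gene excluded", n, min_len))
    return(NULL)
  }
  base <- n %/% 3L; rem <- n %% 3L
  l1 <- base + (rem >= 1L); l2 <- base + (rem >= 2L)
  list(
    five_prime = substr(cds, 1L, l1),
    middle = substr(cds, l1 + 1L, l1 + l2),
    three_prime = substr(cds, l1 + l2 + 1L, n)
  )
}

#' Predict MSL-binding status of CDS thirds and test the 3' bias
#'
#' Scores the 5', middle and 3' third of each gene's CDS with a fitted
#' OPLS-DA model (trained on whole-CDS word frequencies) and runs a paired
#' t-test of the 3' versus 5' scores.
#'
#' @param model An `oplsda_model` fitted on UV-scaled raw CDS frequencies.
#' @param cds Tibble with `gene_id` and `bases` (coding strand).
#' @param k_min,k_max Word range used when the model was trained.
#' @param layout Word-matrix layout used in training.
#' @param alternative Alternative for the paired test (default `"greater"`:
#'   3' scores exceed 5').
#' @return List: `scores` (tibble `gene_id`, `s5`, `smid`, `s3`) and `test`
#'   (tibble with statistic, p_value, n; `insufficient_n` flags n < 2).
#' @export
thirds_bias_test <- function(model, cds, k_min = 2, k_max = 6,
                             layout = c("as_published", "canonical"),
                             alternative = "greater") {
  layout <- match.arg(layout)
  parts <- lapply(cds$bases, split_cds_thirds)
  ok <- !vapply(parts, is.null, TRUE)
  if (!any(ok)) abort("no usable CDS", class = "mslseq_input_error")
  ids <- cds$gene_id[ok]; parts <- parts[ok]
  seqs <- c(vapply(parts, `[[`, "", "five_prime"),
            vapply(parts, `[[`, "", "middle"),
            vapply(parts, `[[`, "", "three_prime"))
  names(seqs) <- paste0(rep(c("p5_", "pm_", "p3_"), each = length(ids)), ids)
  wm <- word_matrix(seqs, k_min, k_max, layout)
  sc <- predict_scores(model, wm)$score
  n <- length(ids)
  scores <- tibble(gene_id = ids, s5 = sc[seq_len(n)],
                   smid = sc[n + seq_len(n)], s3 = sc[2L * n + seq_len(n)])
  if (n < 2L) {
    test <- tibble(statistic = NA_real_, p_value = NA_real_, n = n,
                   insufficient_n = TRUE)
  } else {
    tt <- t.test(scores$s3, scores$s5, paired = TRUE, alternative = alternative)
    test <- tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                   n = n, insufficient_n = FALSE)
  }
  list(scores = scores, test = test)
}

#' Word frequencies under alternative strand/frame conventions
#'
#' `both_strands` is the standard merged counting; `transcribed_only` counts
#' words on the coding strand without reverse-complement merging;
#' `in_frame_only` counts codon-aligned windows (advancing three nucleotides
#' from frame 0) without merging.
#'
#' @param cds CDS string on the coding strand.
#' @param k Word length.
#' @param mode Counting convention.
#' @return Named numeric frequency vector (count / CDS length).
#' @export
strand_frame_variants <- function(cds, k = 3,
                                  mode = c("both_strands", "transcribed_only",
                                           "in_frame_only")) {
  mode <- match.arg(mode)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (mode == "both_strands") {
    cnt <- count_words(cds, k)
    return(cnt / n)
  }
  if (mode == "in_frame_only" && n %% 3L != 0L) {
    warn("CDS length not divisible by 3; truncating to codon boundary")
    n <- (n %/% 3L) * 3L
    cds <- substr(cds, 1L, n)
  }
  step <- if (mode == "in_frame_only") 3L else 1L
  starts <- seq.int(1L, n - k + 1L, by = step)
  wins <- substring(cds, starts, starts + k - 1L)
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins)) return(setNames(numeric(), character()))
  table(wins) |> c() |> (\(x) x / n)()
}

# relative synonymous codon usage from pooled codon counts
rscu_table <- function(cds_list) {
  codons <- all_words(3L)
  aa <- Biostrings::GENETIC_CODE[codons]
  counts <- setNames(numeric(length(codons)), codons)
  for (s in cds_list) {
    s <- toupper(s)
    n <- (nchar(s) %/% 3L) * 3L
    cds_codons <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    tb <- table(cds_codons[cds_codons %in% codons])
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  fam_size <- table(aa)
  fam_mean <- tapply(counts, aa[names(counts)], mean)
  tibble(
    codon = codons, amino_acid = unname(aa),
    count = unname(counts),
    rscu = as.vector(counts / fam_mean[aa]),
    degenerate = unname(fam_size[aa] > 1) & !aa %in% "*"
  )
}

#' Compare codon usage between two CDS sets
#'
#' Computes relative synonymous codon usage (RSCU: each codon's count
#' divided by the mean count of its synonymous family) from the pooled codons
#' of each set and runs a paired t-test across the 59 degenerate
#' (non-stop, non-unique) codons. The test is applied on the log2 RSCU scale:
#' raw RSCU differences sum to exactly zero by construction (each family's
#' RSCU totals its size in both sets), so a paired t-test on raw values is
#' identically null; the log transform breaks that linear constraint while
#' preserving "no preference shift" as the null.
#'
#' @param set_a,set_b Character vectors of CDS (coding strand; lengths are
#'   truncated to codon boundaries).
#' @param floor_rscu Lower bound applied before taking logs (default 0.01).
#' @return List: `usage` (per-codon tibble with `rscu_a`, `rscu_b`) and
#'   `test` (statistic, p_value, n_codons; comparisons where all differences
#'   vanish, e.g. a set against itself, are flagged and give p = NA).
#' @export
codon_usage_compare <- function(set_a, set_b, floor_rscu = 0.01) {
  if (!length(set_a) || !length(set_b)) {
    abort("both CDS sets must be non-empty", class = "mslseq_input_error")
  }
  a <- rscu_table(set_a); b <- rscu_table(set_b)
  usage <- tibble(codon = a$codon, amino_acid = a$amino_acid,
                  rscu_a = a$rscu, rscu_b = b$rscu,
                  degenerate = a$degenerate)
  d <- usage |> filter(.data$degenerate, is.finite(.data$rscu_a),
                       is.finite(.data$rscu_b))
  la <- log2(pmax(d$rscu_a, floor_rscu))
  lb <- log2(pmax(d$rscu_b, floor_rscu))
  if (nrow(d) < 2L || sd(la - lb) == 0) {
    test <- tibble(statistic = NA_real_, p_value = NA_real_,
                   n_codons = nrow(d), degenerate_test = TRUE)
  } else {
    tt <- t.test(la, lb, paired = TRUE)
    test <- tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                   n_codons = nrow(d), degenerate_test = FALSE)
  }
  list(usage = usage, test = test)
}

#' Standard two-group comparisons
#'
#' Wraps the tests used throughout the analysis: Mann-Whitney U
#' (exact when both groups have at most 20 observations and no ties),
#' paired t, and Spearman correlation.
#'
#' @param values_a,values_b Numeric vectors.
#' @param test One of `"mann_whitney"`, `"paired_t"`, `"spearman"`.
#' @param alternative Two-sided by default.
#' @return Tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `alternative`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney", "paired_t", "spearman"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (test == "paired_t" || test == "spearman") {
    if (length(values_a) != length(values_b)) {
      abort("paired tests need equal-length vectors", class = "mslseq_input_error")
    }
  }
  res <- switch(
    test,
    mann_whitney = {
      exact <- length(values_a) <= 20 && length(values_b) <= 20 &&
        !anyDuplicated(c(values_a, values_b))
      wilcox.test(values_a, values_b, alternative = alternative, exact = exact)
    },
    paired_t = t.test(values_a, values_b, paired = TRUE,
                      alternative = alternative),
    spearman = suppressWarnings(
      cor.test(values_a, values_b, method = "spearman",
               alternative = alternative))
  )
  tibble(test = test, statistic = unname(res$statistic),
         p_value = res$p.value, n_a = length(values_a),
         n_b = length(values_b), alternative = alternative)
}
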