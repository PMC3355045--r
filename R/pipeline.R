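# End-to-end orchestration: synthesize (or load) the dataset, derive gene
# features, build word matrices, fit the PCA and OPLS-DA models, extract
# motifs, call peaks, and assemble the report bundle. Deterministic for a
# fixed seed; the single master seed fans out to named sub-streams.

#' Pipeline configuration
#'
#' Collects every fixed constant of the analysis: the word range 2-6, the
#' 500 bp promoter, the 2/3 train fraction, the strong/weak binding cutoffs
#' (1.0 / 0.5 log2), the expressed window (6-10), the aligner parameters and
#' the peak-caller thresholds (3 SD, 360 bp span, 360 bp gap, 5 probes).
#'
#' @param synth A [synth_config()] describing the synthetic dataset.
#' @param k_min,k_max Word length range.
#' @param promoter_bp Promoter length.
#' @param train_fraction Fraction of each class used for training.
#' @param strong_cut,weak_cut,expr_window Gene classification thresholds.
#' @param aligner An [aligner_params()] list.
#' @param peak_sd_mult,peak_min_span,peak_max_gap,peak_min_probes Peak-caller
#'   thresholds.
#' @param n_orth Orthogonal components for the OPLS-DA models (`"auto"` or a
#'   count).
#' @param run_random_null Also run the random-group null (adds runtime).
#' @param n_null_groups,null_group_size Random-null geometry (7 x 100).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), k_min = 2, k_max = 6,
                            promoter_bp = 500, train_fraction = 2 / 3,
                            strong_cut = 1.0, weak_cut = 0.5,
                            expr_window = c(6, 10),
                            aligner = aligner_params(),
                            peak_sd_mult = 3, peak_min_span = 360,
                            peak_max_gap = 360, peak_min_probes = 5,
                            n_orth = "auto",
                            run_random_null = FALSE, n_null_groups = 7,
                            null_group_size = 100, seed = 1L) {
  cfg <- as.list(environment())
  cfg$synth$seed <- cfg$seed   # one master seed drives everything
  structure(cfg, class = "pipeline_config")
}

# stratified train/test split, deterministic per seed
train_test_split <- function(ids, labels, train_fraction, seed) {
  f <- factor(labels)
  train <- logical(length(ids))
  withr::with_seed(seed, {
    for (lv in levels(f)) {
      idx <- which(f == lv)
      n_tr <- round(length(idx) * train_fraction)
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

#' Fraction of flagged genes per MSL-enrichment bin
#'
#' Genes are binned by their average MSL enrichment (mean of the three
#' binding values); each occupied bin reports the fraction of its genes
#' carrying the presence flag. Empty bins are absent (missing, not zero).
#'
#' @param class_table Output of [classify_genes()] (needs `gene_id`,
#'   `avg_msl`).
#' @param presence Tibble `gene_id`, `present` (logical).
#' @param bin_width Enrichment bin width (default 0.2 log2 units).
#' @return Tibble `bin_lo`, `bin_hi`, `n`, `fraction`.
#' @export
binned_enrichment_summary <- function(class_table, presence, bin_width = 0.2) {
  df <- class_table |>
    inner_join(presence, by = "gene_id") |>
    mutate(bin_lo = floor(.data$avg_msl / bin_width) * bin_width)
  if (!nrow(df)) abort("no genes shared between tables", class = "mslseq_input_error")
  df |>
    group_by(.data$bin_lo) |>
    summarise(n = dplyr::n(), fraction = mean(.data$present), .groups = "drop") |>
    mutate(bin_hi = .data$bin_lo + bin_width) |>
    select("bin_lo", "bin_hi", "n", "fraction") |>
    arrange(.data$bin_lo)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages: synthesize the dataset; write and re-read it through the standard
#' formats; derive gene features; genome-wide feature PCA (30 observations,
#' raw and AT-normalized); gene-class PCA; promoter and CDS OPLS-DA with a
#' stratified 2/3-1/3 train/test split and held-out Y-prediction tests;
#' promoter motif extraction with FPR-calibrated cutoff and presence
#' fractions; insulator peak calling, TSS distances and MOF co-localization;
#' CDS-thirds 3' bias; optionally the random-group null.
#'
#' @param config A [pipeline_config()].
#' @param outdir Directory for the written dataset and reports (default: a
#'   temporary directory).
#' @param verbose Log stage timings to stderr.
#' @return A named list (report bundle); see the elements written by each
#'   stage, plus `provenance` (config hash, seed, timestamps).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- outdir %||% tempfile("mslseq_run_")
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, code) {
    t0 <- Sys.time()
    on.exit(say("[%s] %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "mslseq_stage_error")
    })
  }
  report <- list()

  ds <- stage("synth", generate_dataset(config$synth))
  paths <- stage("write", write_dataset(ds, outdir))
  genes <- stage("features", parse_annotation(paths[["annotation"]]))
  genome <- Biostrings::readDNAStringSet(paths[["genome"]])
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrlen <- chrom_lengths_of(genome)
  feats <- derive_features(genes, chrlen, config$promoter_bp)
  feats <- extract_sequences(feats, genome)

  truth_genes <- ds$truth$genes

  # ---- genome-wide feature matrix: 6 classes x chromosome arms -------------
  report$feature_pca <- stage("feature_pca", {
    pooled <- feats |>
      mutate(obs_id = paste(.data$chrom, .data$feature_class, sep = ":")) |>
      select("obs_id", "bases")
    wm <- word_matrix(pooled, config$k_min, config$k_max, "as_published")
    raw_pca <- fit_pca(scale_matrix(wm, "uv_scaled"))
    norm_pca <- fit_pca(scale_matrix(at_normalize(wm), "centered"))
    list(
      n_obs = nrow(wm), n_vars = ncol(wm),
      raw = raw_pca, at_normalized = norm_pca,
      at_correlation = tibble(
        model = c("raw", "at_normalized"),
        spearman_pc1_at = c(
          suppressWarnings(cor(raw_pca$scores[, 1L], at_content(wm),
                               method = "spearman")),
          suppressWarnings(cor(norm_pca$scores[, 1L], at_content(wm),
                               method = "spearman"))))
    )
  })

  # ---- gene binding, classification ----------------------------------------
  report$classes <- stage("classify", {
    tracks <- lapply(paths[grep("^track_", names(paths))], read_bedgraph)
    names(tracks) <- sub("^track_", "", names(tracks))
    binding <- gene_binding_table(tracks[c("MSL1", "MSL3", "MOF")], genes)
    expr <- read.table(paths[["expression"]], header = TRUE, sep = "\t")
    class_table <- classify_genes(binding, expr, config$strong_cut,
                                  config$weak_cut, config$expr_window)
    truth_cmp <- class_table |>
      inner_join(truth_genes |> select("gene_id", truth_class = "class"),
                 by = "gene_id")
    acc <- truth_cmp |>
      filter(.data$truth_class %in% c("strong", "weak")) |>
      summarise(agree = mean((.data$truth_class == "strong" &
                                .data$class == "strong_expressed") |
                             (.data$truth_class == "weak" &
                                .data$class == "weak_expressed")))
    list(table = class_table, binding = binding,
         label_recovery = acc$agree, tracks = tracks)
  })
  class_table <- report$classes$table

  # ---- class PCA (promoter feature, chrom x class pools) -------------------
  report$class_pca <- stage("class_pca", {
    pooled <- feats |>
      filter(.data$feature_class == "promoter") |>
      inner_join(class_table |> select("gene_id", "class"),
                 by = c(owner_gene = "gene_id")) |>
      filter(.data$class %in% c("strong_expressed", "weak_expressed",
                                "unexpressed")) |>
      mutate(obs_id = paste(.data$chrom, .data$class, sep = ":")) |>
      select("obs_id", "bases")
    wm <- word_matrix(pooled, config$k_min, config$k_max, "as_published")
    fit_pca(scale_matrix(at_normalize(wm), "centered"))
  })

  # ---- promoter OPLS-DA: train/test, prediction, motif ---------------------
  model_genes <- class_table |>
    filter(.data$class %in% c("strong_expressed", "weak_expressed")) |>
    mutate(label = ifelse(.data$class == "strong_expressed", "strong", "weak"))
  promoters <- feats |>
    filter(.data$feature_class == "promoter") |>
    group_by(.data$owner_gene) |>
    summarise(bases = paste(.data$bases, collapse = ""), .groups = "drop") |>
    inner_join(model_genes |> select("gene_id", "label"),
               by = c(owner_gene = "gene_id")) |>
    filter(nchar(.data$bases) >= config$k_max)

  report$promoter_model <- stage("oplsda_promoter", {
    train <- train_test_split(promoters$owner_gene, promoters$label,
                              config$train_fraction,
                              substream_seed(config$seed, "split_promoter"))
    wm_all <- word_matrix(setNames(promoters$bases, promoters$owner_gene),
                          config$k_min, config$k_max, "canonical")
    wm_tr <- scale_matrix(
      word_matrix(setNames(promoters$bases[train], promoters$owner_gene[train]),
                  config$k_min, config$k_max, "canonical"), "uv_scaled")
    fit <- fit_oplsda(wm_tr, promoters$label[train], n_orth = config$n_orth,
                      folds = 7, seed = substream_seed(config$seed, "cv_promoter"))
    test_scores <- predict_scores(fit, wm_all[!train, , drop = FALSE]) |>
      mutate(label = promoters$label[!train])
    mw <- compare_groups(test_scores$score[test_scores$label == "strong"],
                         test_scores$score[test_scores$label == "weak"],
                         "mann_whitney", alternative = "greater")
    list(model = fit, train = train, test_scores = test_scores, test = mw)
  })

  report$motif <- stage("motif", {
    fit <- report$promoter_model$model
    train <- report$promoter_model$train
    loadings <- sort(fit$predictive_loadings, decreasing = TRUE)
    words <- tibble(word = names(loadings), loading = unname(loadings)) |>
      filter(.data$loading > 0)
    pos <- promoters$bases[train & promoters$label == "strong"]
    neg <- promoters$bases[train & promoters$label == "weak"]
    motifs <- build_motifs(words, pos, neg, config$aligner)
    if (!length(motifs)) return(list(motifs = motifs))
    pwm <- motifs[[1L]]
    test_strong <- promoters$bases[!train & promoters$label == "strong"]
    test_weak <- promoters$bases[!train & promoters$label == "weak"]
    presence_all <- tibble(
      gene_id = promoters$owner_gene,
      present = scan_scores(pwm, promoters$bases, 1L) >= pwm$cutoff
    )
    list(
      motifs = motifs, pwm = pwm,
      presence_fraction = tibble(
        set = c("train_strong", "train_weak", "test_strong", "test_weak"),
        fraction = c(
          motif_presence_fraction(pwm, pos, config$promoter_bp),
          motif_presence_fraction(pwm, neg, config$promoter_bp),
          motif_presence_fraction(pwm, test_strong, config$promoter_bp),
          motif_presence_fraction(pwm, test_weak, config$promoter_bp))),
      by_enrichment_bin = binned_enrichment_summary(class_table, presence_all),
      recovery_cor = planted_pwm_correlation(pwm, config$synth$planted_pwm)
    )
  })

  # ---- peaks, TSS distances, co-localization -------------------------------
  report$peaks <- stage("peaks", {
    tracks <- report$classes$tracks
    beaf <- call_regions(tracks$BEAF, config$peak_sd_mult,
                         config$peak_min_span, config$peak_max_gap,
                         config$peak_min_probes)
    dist <- tss_peak_distance(genes, beaf) |>
      inner_join(class_table |> select("gene_id", "class"), by = "gene_id")
    dist_test <- compare_groups(
      dist$distance[dist$class == "weak_expressed"],
      dist$distance[dist$class == "strong_expressed"],
      "mann_whitney", alternative = "greater")
    # promoter-overlapping anchors at genes without strong gene-body signal
    # (the co-localization readout targets promoter-proximal MOF, so strong
    # genes, whose exonic enrichment dwarfs the promoter signal, are left out)
    anchor_info <- lapply(seq_len(nrow(beaf)), function(i) {
      g <- genes[genes$chrom == beaf$chrom[i], ]
      d <- abs(g$tss - beaf$center[i])
      if (!length(d) || min(d) > 500) return(NULL)
      list(strand = g$strand[which.min(d)], gene_id = g$gene_id[which.min(d)])
    })
    keep <- !vapply(anchor_info, is.null, TRUE)
    anchors <- beaf[keep, ] |>
      mutate(strand = vapply(anchor_info[keep], `[[`, "", "strand"),
             gene_id = vapply(anchor_info[keep], `[[`, "", "gene_id")) |>
      left_join(class_table |> select("gene_id", "class"), by = "gene_id") |>
      filter(.data$class != "strong_expressed" | is.na(.data$class))
    coloc <- binned_colocalization(tracks$MOF, anchors, bin = 100, span = 2000)
    list(regions = beaf, tss_distances = dist, distance_test = dist_test,
         colocalization = coloc,
         coverage = coverage_fraction(beaf, chrlen))
  })

  # ---- CDS model and 3' bias ------------------------------------------------
  cds_tbl <- feats |>
    filter(.data$feature_class == "cds") |>
    group_by(.data$owner_gene) |>
    arrange(ifelse(.data$strand == "-", -.data$start, .data$start),
            .by_group = TRUE) |>
    summarise(bases = paste(.data$bases, collapse = ""), .groups = "drop") |>
    inner_join(model_genes |> select("gene_id", "label"),
               by = c(owner_gene = "gene_id"))
  report$cds_model <- stage("oplsda_cds", {
    train <- train_test_split(cds_tbl$owner_gene, cds_tbl$label,
                              config$train_fraction,
                              substream_seed(config$seed, "split_cds"))
    wm_tr <- scale_matrix(
      word_matrix(setNames(cds_tbl$bases[train], cds_tbl$owner_gene[train]),
                  config$k_min, config$k_max, "canonical"), "uv_scaled")
    fit <- fit_oplsda(wm_tr, cds_tbl$label[train], n_orth = config$n_orth,
                      folds = 7, seed = substream_seed(config$seed, "cv_cds"))
    wm_te <- word_matrix(setNames(cds_tbl$bases[!train], cds_tbl$owner_gene[!train]),
                         config$k_min, config$k_max, "canonical")
    test_scores <- predict_scores(fit, wm_te) |>
      mutate(label = cds_tbl$label[!train])
    mw <- compare_groups(test_scores$score[test_scores$label == "strong"],
                         test_scores$score[test_scores$label == "weak"],
                         "mann_whitney", alternative = "greater")
    thirds <- thirds_bias_test(
      fit, tibble(gene_id = cds_tbl$owner_gene[!train],
                  bases = cds_tbl$bases[!train]),
      config$k_min, config$k_max, "canonical")
    list(model = fit, train = train, test = mw, thirds = thirds)
  })

  # ---- random-group null ----------------------------------------------------
  if (config$run_random_null) {
    report$random_null <- stage("random_null", {
      pool <- cds_tbl$bases
      random_group_null(pool, config$n_null_groups, config$null_group_size,
                        seed = substream_seed(config$seed, "random_null"),
                        k_min = config$k_min, k_max = config$k_max)
    })
  }

  report$truth <- ds$truth
  report$provenance <- list(
    seed = config$seed, config_hash = rlang::hash(unclass(config)),
    outdir = outdir, timestamp = format(Sys.time(), tz = "UTC")
  )
  report
}

#' Mean per-position correlation between a motif and a reference PWM
#'
#' Slides the motif along the reference in both orientations and returns the
#' best mean per-position Pearson correlation of the base-probability
#' columns; used to score recovery of a planted motif.
#'
#' @param pwm A `pwm_motif`.
#' @param reference L x 4 probability matrix (or `pwm_motif`).
#' @return The best mean per-column correlation over offsets/orientations.
#' @export
pwm_match_correlation <- function(pwm, reference) {
  if (inherits(reference, "pwm_motif")) reference <- reference$columns
  rec <- pwm$columns
  best <- -Inf
  for (pl in list(as.matrix(reference), rc_mat(as.matrix(reference)))) {
    colnames(pl) <- BASES
    La <- nrow(rec); Lb <- nrow(pl)
    for (s in seq(-La + 1L, Lb - 1L)) {
      ia <- which(seq_len(La) + s >= 1L & seq_len(La) + s <= Lb)
      if (length(ia) < min(La, Lb, 5L)) next
      r <- mean(vapply(ia, function(i)
        suppressWarnings(cor(rec[i, ], pl[i + s, ])), 0), na.rm = TRUE)
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

planted_pwm_correlation <- function(pwm, planted) {
  pwm_match_correlation(pwm, planted)
}
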