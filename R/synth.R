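# Synthetic genome / annotation / signal / expression generator with known
# ground truth. The generator emulates the statistical structure of
# ChIP-chip-era inputs: gene models with promoter/UTR/CDS/intron structure on five
# chromosome arms, a planted promoter PWM carried by a tunable fraction of
# strong vs weak genes (defaults 0.44 / 0.18), CDS word enrichment rising
# from the 5' to the 3' third in strong genes, three MSL-protein probe tracks
# with exonic gene-body enrichment, insulator-like promoter peaks, and
# replicate expression values concentrated in the 6-10 window.

#' Default planted promoter PWM
#'
#' A 10-position PWM with a CGATA-like core and 0.95 consensus base per
#' position (total information content about 15 bits), emulating a sharp
#' insulator-class promoter motif.
#'
#' @return A 10 x 4 probability matrix (rows = positions, columns A,C,G,T).
#' @export
default_planted_pwm <- function() {
  consensus <- strsplit("TATCGATAGA", "")[[1L]]
  m <- matrix(0.05 / 3, length(consensus), 4L, dimnames = list(NULL, BASES))
  m[cbind(seq_along(consensus), match(consensus, BASES))] <- 0.95
  m
}

#' Synthetic-dataset configuration
#'
#' Default parameters describe the modeled conditions: motif insertion fractions 0.44
#' (strong) and 0.18 (weak) within the 500 bp promoter, insulator-peak
#' fractions 0.49 / 0.13, CDS enrichment multipliers 1/2/3 across the 5',
#' middle and 3' thirds of strong genes, MSL gene-body enrichment 1.2 (strong)
#' vs 0.2 (weak) in log2 units, and expression in the 6-10 window (strong mean
#' 8.37, weak 7.44; unexpressed below 6).
#'
#' @param n_genes_per_class Genes per class (strong, weak, unexpressed).
#' @param class_names Class labels.
#' @param chroms Chromosome arm names.
#' @param feature_length_means Mean bp of `utr5`, `cds`, `intron`, `utr3` and
#'   the `intergenic` gap between gene units (gap must exceed the promoter by
#'   at least 100 bp).
#' @param background_base_probs A,C,G,T probabilities of the background
#'   sequence (sum 1).
#' @param planted_pwm L x 4 probability matrix planted in promoters.
#' @param motif_insert_prob Named per-class insertion probability.
#' @param cds_enriched_words Words planted in strong-gene CDS.
#' @param cds_third_multipliers Relative planting rate in the 5'/mid/3' third.
#' @param cds_word_rate Expected plantings per word per kb at multiplier 1.
#' @param promoter_enriched_words Words carrying the class-dependent
#'   compositional bias of strong-gene promoters.
#' @param promoter_word_rate Baseline expected plantings per word per
#'   promoter.
#' @param promoter_word_enrichment Fold-increase of the planting rate in
#'   strong-gene promoters.
#' @param probe_spacing Probe midpoint spacing in bp.
#' @param signal_gene_enrichment Named per-class mean exon log2 enrichment.
#' @param signal_noise_sd Probe-level noise SD (log2).
#' @param gene_effect_sd SD of the per-gene, per-protein enrichment mean.
#' @param peak_insert_prob Per-class probability of an insulator-like peak
#'   150 bp upstream of the TSS.
#' @param peak_amplitude,peak_width Gaussian bump height (log2) and SD (bp).
#' @param mof_promoter_bump MOF co-bump height at planted peaks (log2).
#' @param expression_window Low/high bounds of the expressed window.
#' @param expression_means Named per-class mean expression.
#' @param promoter_bp Promoter length.
#' @param seed Master seed; all randomness derives from it via named
#'   sub-streams.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(
    n_genes_per_class = 150,
    class_names = c("strong", "weak", "unexpressed"),
    chroms = c("2L", "2R", "3L", "3R", "X"),
    feature_length_means = c(utr5 = 200, cds = 900, intron = 300, utr3 = 300,
                             intergenic = 1200),
    background_base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    planted_pwm = default_planted_pwm(),
    motif_insert_prob = c(strong = 0.44, weak = 0.18, unexpressed = 0.10),
    cds_enriched_words = c("GACGTC", "AGGCAG", "CAGGAC", "GGTCGA", "ACGGAG",
                           "CGAGGT", "GTCAGC", "AGCGGA", "CCGTAG", "GAGCCA"),
    cds_third_multipliers = c(1, 2, 3),
    cds_word_rate = 1.5,
    promoter_enriched_words = c("GGCTAA", "TCCGGT", "ATGGCG", "CGTTGC",
                                "GCACGG", "TAGCCG", "GTGGAC", "CCATCG",
                                "AGCGTT", "CGGATT"),
    promoter_word_rate = 0.5,
    promoter_word_enrichment = 3,
    probe_spacing = 100,
    signal_gene_enrichment = c(strong = 1.2, weak = 0.2, unexpressed = 0),
    signal_noise_sd = 0.1,
    gene_effect_sd = 0.02,
    peak_insert_prob = c(strong = 0.49, weak = 0.13, unexpressed = 0.10),
    peak_amplitude = 4, peak_width = 250,
    mof_promoter_bump = 0.5,
    expression_window = c(6, 10),
    expression_means = c(strong = 8.37, weak = 7.44, unexpressed = 4.5),
    promoter_bp = 500,
    seed = 1L) {
  cfg <- as.list(environment())
  planted_pwm <- as.matrix(planted_pwm)
  if (nrow(planted_pwm) > 0 &&
      (ncol(planted_pwm) != 4L || any(planted_pwm < 0) ||
       any(abs(rowSums(planted_pwm) - 1) > 1e-9))) {
    abort("planted_pwm positions must be 4 non-negative values summing to 1",
          class = "mslseq_config_error")
  }
  if (abs(sum(background_base_probs) - 1) > 1e-9 || any(background_base_probs < 0)) {
    abort("background_base_probs must be non-negative and sum to 1",
          class = "mslseq_config_error")
  }
  probs <- c(motif_insert_prob, peak_insert_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("insertion probabilities must lie in [0, 1]", class = "mslseq_config_error")
  }
  if (any(feature_length_means < 6)) {
    abort("feature lengths must be at least the longest word (6 bp)",
          class = "mslseq_config_error")
  }
  if (feature_length_means[["intergenic"]] < promoter_bp + 100) {
    abort("intergenic gap must exceed promoter_bp by >= 100 so promoters fit",
          class = "mslseq_config_error")
  }
  if (!all(class_names %in% names(motif_insert_prob)) ||
      !all(class_names %in% names(signal_gene_enrichment))) {
    abort("per-class parameters must name every class", class = "mslseq_config_error")
  }
  structure(cfg, class = "synth_config")
}

#' Plant one motif instance in a sequence
#'
#' Replaces bases at `position` with a draw from the PWM (column-wise base
#' sampling, no indels); uses the current RNG state.
#'
#' @param sequence DNA string.
#' @param pwm L x 4 probability matrix (or `pwm_motif`).
#' @param position 0-based insertion offset.
#' @return The modified sequence.
#' @export
plant_motif <- function(sequence, pwm, position) {
  if (inherits(pwm, "pwm_motif")) pwm <- pwm$columns
  pwm <- as.matrix(pwm)
  L <- nrow(pwm)
  if (L == 0L) return(sequence)
  if (position < 0 || position + L > nchar(sequence)) {
    abort("motif does not fit at `position`", class = "mslseq_bounds_error")
  }
  draw <- vapply(seq_len(L), function(i)
    sample(BASES, 1L, prob = pwm[i, ]), "")
  substr(sequence, position + 1L, position + L) <-
    paste(draw, collapse = "")
  sequence
}

# sample a length around a mean (uniform within +/- 20%)
len_around <- function(mean, lo = 6L) {
  max(lo, as.integer(round(runif(1L, 0.8, 1.2) * mean)))
}

#' Generate a synthetic dataset with ground truth
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset` list: `genome` (`DNAStringSet`), `annotation`
#'   (GFF3-style record tibble), `tracks` (named probe-track tibbles for
#'   MSL1, MSL3, MOF and BEAF), `expression` (gene x 3 replicates),
#'   `truth` (list of `genes` and `peaks` tibbles) and `config`.
#'   Deterministic for a fixed config (same config, same seed give
#'   byte-identical written files).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  fl <- config$feature_length_means
  classes <- config$class_names
  n_total <- config$n_genes_per_class * length(classes)
  gene_class <- rep(classes, length.out = n_total)    # interleaved
  gene_chrom <- rep(config$chroms, length.out = n_total)

  # ---- gene structure ------------------------------------------------------
  genes <- with_substream(config$seed, "structure", {
    rows <- vector("list", n_total)
    cursor <- setNames(rep(0L, length(config$chroms)), config$chroms)
    for (i in seq_len(n_total)) {
      ch <- gene_chrom[i]
      gap <- len_around(fl[["intergenic"]], lo = config$promoter_bp + 100L)
      u5 <- len_around(fl[["utr5"]], 20L)
      cds <- len_around(fl[["cds"]], 90L); cds <- (cds %/% 3L) * 3L
      intr <- len_around(fl[["intron"]], 60L)
      u3 <- len_around(fl[["utr3"]], 20L)
      strand <- sample(c("+", "-"), 1L)
      cds1 <- (cds %/% 2L %/% 3L) * 3L
      cds2 <- cds - cds1
      s0 <- cursor[[ch]] + gap
      # transcript laid left-to-right in transcription order, then mirrored
      seg <- c(u5, cds1, intr, cds2, u3)
      ends <- s0 + cumsum(seg)
      starts <- c(s0, ends[-length(ends)])
      iv <- cbind(starts, ends)
      span <- c(s0, ends[5L])
      if (strand == "-") {
        # mirror within the span so the TSS sits at the right end
        iv <- cbind(span[1L] + span[2L] - iv[, 2L], span[1L] + span[2L] - iv[, 1L])
        iv <- iv[5L:1L, , drop = FALSE]
      }
      # iv rows now genomic-sorted; ord maps each row to its transcript part
      ord <- if (strand == "+") 1:5 else 5:1
      rows[[i]] <- tibble(
        gene_id = sprintf("g%04d", i), chrom = ch, strand = strand,
        class = gene_class[i],
        span_start = span[1L], span_end = span[2L],
        tss = if (strand == "+") span[1L] else span[2L] - 1L,
        utr5 = list(matrix(iv[which(ord == 1L), ], 1L)),
        cds = list(iv[sort(which(ord %in% c(2L, 4L))), , drop = FALSE]),
        intron = list(matrix(iv[which(ord == 3L), ], 1L)),
        utr3 = list(matrix(iv[which(ord == 5L), ], 1L)),
        cds_len = cds
      )
      cursor[[ch]] <- span[2L]
    }
    bind_rows(rows)
  })
  chrom_lengths <- genes |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$span_end) + as.integer(fl[["intergenic"]]),
              .groups = "drop")
  chrom_lengths <- setNames(chrom_lengths$len, chrom_lengths$chrom)[config$chroms]

  # ---- background sequence (as per-base vectors while planting) ------------
  chrvec <- with_substream(config$seed, "genome", {
    setNames(lapply(config$chroms, function(ch)
      sample(BASES, chrom_lengths[[ch]], replace = TRUE,
             prob = config$background_base_probs)),
      config$chroms)
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  # ---- CDS word enrichment with 3' gradient (strong genes) -----------------
  chrvec <- with_substream(config$seed, "cds_words", {
    for (i in which(genes$class == "strong")) {
      g <- genes[i, ]
      cdsm <- g$cds[[1L]]
      idx <- unlist(lapply(seq_len(nrow(cdsm)), function(j)
        (cdsm[j, 1L] + 1L):cdsm[j, 2L]))
      cds_chars <- chrvec[[g$chrom]][idx]
      if (g$strand == "-") cds_chars <- rev(unname(comp[cds_chars]))
      n <- length(cds_chars)
      cut1 <- ceiling(n / 3); cut2 <- ceiling(2 * n / 3)
      third_bounds <- rbind(c(1, cut1), c(cut1 + 1, cut2), c(cut2 + 1, n))
      for (t in 1:3) {
        lo <- third_bounds[t, 1L]; hi <- third_bounds[t, 2L]
        width <- hi - lo + 1L
        for (w in config$cds_enriched_words) {
          lam <- config$cds_word_rate * config$cds_third_multipliers[t] * width / 1000
          k <- rpois(1L, lam)
          if (k == 0L) next
          wl <- strsplit(w, "")[[1L]]
          maxpos <- width - length(wl) + 1L
          if (maxpos < 1L) next
          for (p in (lo - 1L) + sample.int(maxpos, k, replace = TRUE)) {
            cds_chars[p:(p + length(wl) - 1L)] <- wl
          }
        }
      }
      if (g$strand == "-") cds_chars <- rev(unname(comp[cds_chars]))
      chrvec[[g$chrom]][idx] <- cds_chars
    }
    chrvec
  })

  # ---- promoter word-composition bias --------------------------------------
  chrvec <- with_substream(config$seed, "promoter_words", {
    for (i in seq_len(n_total)) {
      g <- genes[i, ]
      mult <- if (g$class == "strong") config$promoter_word_enrichment else 1
      if (g$strand == "+") {
        lo <- max(0L, g$span_start - config$promoter_bp); hi <- g$span_start
      } else {
        lo <- g$span_end
        hi <- min(chrom_lengths[[g$chrom]], g$span_end + config$promoter_bp)
      }
      width <- hi - lo
      if (width < 10L) next
      for (w in config$promoter_enriched_words) {
        k <- rpois(1L, config$promoter_word_rate * mult * width /
                     config$promoter_bp)
        if (k == 0L) next
        wl <- strsplit(w, "")[[1L]]
        maxpos <- width - length(wl)
        if (maxpos < 1L) next
        for (p in lo + sample.int(maxpos, k, replace = TRUE)) {
          chrvec[[g$chrom]][(p + 1L):(p + length(wl))] <- wl
        }
      }
    }
    chrvec
  })

  # ---- planted promoter motif ----------------------------------------------
  L <- nrow(config$planted_pwm)
  motif_res <- with_substream(config$seed, "motif", {
    planted <- logical(n_total); mpos <- rep(NA_integer_, n_total)
    for (i in seq_len(n_total)) {
      g <- genes[i, ]
      if (runif(1L) >= config$motif_insert_prob[[g$class]]) next
      if (g$strand == "+") {
        lo <- max(0L, g$span_start - config$promoter_bp); hi <- g$span_start - L
      } else {
        lo <- g$span_end
        hi <- min(chrom_lengths[[g$chrom]], g$span_end + config$promoter_bp) - L
      }
      if (hi < lo || L == 0L) next
      p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      draw <- vapply(seq_len(L), function(j)
        sample(BASES, 1L, prob = config$planted_pwm[j, ]), "")
      chrvec[[g$chrom]][(p + 1L):(p + L)] <- draw
      planted[i] <- TRUE; mpos[i] <- p
    }
    list(chrvec = chrvec, planted = planted, mpos = mpos)
  })
  chrvec <- motif_res$chrvec
  genes$motif_planted <- motif_res$planted
  genes$motif_pos <- motif_res$mpos
  chrseq <- vapply(chrvec, paste, "", collapse = "")

  # ---- insulator-like peaks -------------------------------------------------
  peaks <- with_substream(config$seed, "peaks", {
    rows <- list()
    for (i in seq_len(n_total)) {
      g <- genes[i, ]
      if (runif(1L) >= config$peak_insert_prob[[g$class]]) next
      ctr <- if (g$strand == "+") g$tss - 150L else g$tss + 150L
      rows[[length(rows) + 1L]] <- tibble(
        chrom = g$chrom, center = ctr,
        amplitude = rnorm(1L, config$peak_amplitude, 0.3),
        gene_id = g$gene_id, strand = g$strand
      )
    }
    proto <- tibble(chrom = character(), center = integer(),
                    amplitude = numeric(), gene_id = character(),
                    strand = character())
    bind_rows(c(list(proto), rows))
  })

  # ---- probe tracks ---------------------------------------------------------
  tracks <- with_substream(config$seed, "signal", {
    proteins <- c("MSL1", "MSL3", "MOF")
    effects <- matrix(
      rnorm(n_total * 3L,
            mean = rep(unlist(config$signal_gene_enrichment[genes$class]), 3L),
            sd = config$gene_effect_sd),
      n_total, 3L, dimnames = list(genes$gene_id, proteins))
    out <- list()
    for (pr in c(proteins, "BEAF")) {
      tr <- list()
      for (ch in config$chroms) {
        pos <- seq.int(config$probe_spacing %/% 2L, chrom_lengths[[ch]] - 1L,
                       by = config$probe_spacing)
        val <- rnorm(length(pos), 0, config$signal_noise_sd)
        if (pr != "BEAF") {
          for (i in which(genes$chrom == ch)) {
            exm <- rbind(genes$utr5[[i]], genes$cds[[i]], genes$utr3[[i]])
            for (j in seq_len(nrow(exm))) {
              hit <- pos >= exm[j, 1L] & pos < exm[j, 2L]
              val[hit] <- val[hit] + effects[i, pr]
            }
          }
        }
        pk <- peaks[nrow(peaks) > 0 & peaks$chrom == ch, ]
        if (nrow(pk)) {
          bump_amp <- if (pr == "BEAF") pk$amplitude
            else if (pr == "MOF") rep(config$mof_promoter_bump, nrow(pk))
            else NULL
          if (!is.null(bump_amp)) {
            for (q in seq_len(nrow(pk))) {
              d <- pos - pk$center[q]
              val <- val + bump_amp[q] * exp(-d^2 / (2 * config$peak_width^2))
            }
          }
        }
        tr[[ch]] <- tibble(chrom = ch, pos = as.integer(pos), value = val)
      }
      out[[pr]] <- bind_rows(tr)
    }
    out
  })

  # ---- expression -----------------------------------------------------------
  expression <- with_substream(config$seed, "expression", {
    win <- config$expression_window
    mu <- unlist(config$expression_means[genes$class])
    level <- rnorm(n_total, mu, 0.8)
    expressed <- genes$class != "unexpressed"
    level[expressed] <- pmin(pmax(level[expressed], win[1L] + 0.05), win[2L] - 0.05)
    level[!expressed] <- pmin(level[!expressed], win[1L] - 0.3)
    reps <- matrix(rnorm(n_total * 3L, rep(level, 3L), 0.04), n_total, 3L)
    reps[expressed, ] <- pmin(pmax(reps[expressed, ], win[1L]), win[2L])
    reps[!expressed, ] <- pmin(reps[!expressed, ], win[1L] - 0.2)
    tibble(gene_id = genes$gene_id, rep1 = reps[, 1L], rep2 = reps[, 2L],
           rep3 = reps[, 3L])
  })

  structure(
    list(
      genome = Biostrings::DNAStringSet(unlist(chrseq)),
      annotation = annotation_records(genes),
      tracks = tracks,
      expression = expression,
      truth = list(genes = genes, peaks = peaks,
                   chrom_lengths = chrom_lengths),
      config = config
    ),
    class = "synth_dataset"
  )
}

# GFF3-style records (1-based inclusive) for the synthetic gene models
annotation_records <- function(genes) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rec <- function(type, m, id, parent) {
      tibble(chrom = g$chrom, source = "mslseq_synth", type = type,
             start = m[, 1L] + 1L, end = m[, 2L], strand = g$strand,
             id = id, parent = parent)
    }
    span <- cbind(g$span_start, g$span_end)
    exons <- rbind(g$utr5[[1L]], g$cds[[1L]], g$utr3[[1L]])
    exons <- iv_sort(exons)
    exr <- iv_from_ranges(IRanges::reduce(ranges_from_iv(exons)))
    mrna_id <- paste0(g$gene_id, ".t1")
    rows[[i]] <- bind_rows(
      rec("gene", span, g$gene_id, NA_character_),
      rec("mRNA", span, mrna_id, g$gene_id),
      rec("exon", exr, paste0(mrna_id, ".e", seq_len(nrow(exr))), mrna_id),
      rec("CDS", g$cds[[1L]], paste0(mrna_id, ".c", seq_len(nrow(g$cds[[1L]]))),
          mrna_id)
    )
  }
  bind_rows(rows)
}

#' Write a synthetic dataset to standard file formats
#'
#' FASTA genome, GFF3 annotation (1-based inclusive), one bedGraph per probe
#' track (0-based half-open), a TSV expression table, and the ground truth as
#' JSON.
#'
#' @param ds A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(ds$genome, paths[["genome"]], width = 80L)
  an <- ds$annotation
  attrs <- ifelse(is.na(an$parent), paste0("ID=", an$id),
                  paste0("ID=", an$id, ";Parent=", an$parent))
  gff <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                 an$chrom, an$source, an$type, an$start, an$end, an$strand,
                 ifelse(an$type == "CDS", "0", "."), attrs)
  writeLines(c("##gff-version 3", gff), paths[["annotation"]])
  for (pr in names(ds$tracks)) {
    p <- file.path(dir, paste0("track_", pr, ".bedgraph"))
    write_bedgraph(ds$tracks[[pr]], p)
    paths[[paste0("track_", pr)]] <- p
  }
  write.table(ds$expression, paths[["expression"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$genes <- truth$genes |>
    select(-"utr5", -"cds", -"intron", -"utr3")
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Synthetic sequence sets with planted word enrichment
#'
#' Two classes of background sequences; the enriched class carries each word
#' at `enrichment`-fold the baseline Poisson planting rate. Used for
#' OPLS-DA recovery and null experiments.
#'
#' @param n_per_class Sequences per class.
#' @param len Sequence length (bp).
#' @param words Planted words.
#' @param enrichment Fold-increase of the planting rate in the enriched class.
#' @param base_rate Baseline expected plantings per word per sequence.
#' @param base_probs Background base probabilities.
#' @param seed Seed.
#' @return Tibble with `obs_id`, `class` (`"enriched"`/`"background"`) and
#'   `bases`.
#' @export
synth_word_enriched_seqs <- function(n_per_class = 150, len = 500,
                                     words = c("GACGTC", "AGGCAG", "CAGGAC",
                                               "GGTCGA", "ACGGAG", "CGAGGT",
                                               "GTCAGC", "AGCGGA", "CCGTAG",
                                               "GAGCCA"),
                                     enrichment = 3, base_rate = 0.5,
                                     base_probs = c(0.3, 0.2, 0.2, 0.3),
                                     seed = 1L) {
  withr::with_seed(seed, {
    mk <- function(n, rate, tag) {
      vapply(seq_len(n), function(i) {
        s <- random_dna(len, base_probs)
        for (w in words) {
          k <- rpois(1L, rate)
          if (k == 0L) next
          for (p in sample.int(len - nchar(w) + 1L, k, replace = TRUE)) {
            substr(s, p, p + nchar(w) - 1L) <- w
          }
        }
        s
      }, "")
    }
    tibble(
      obs_id = sprintf("s%04d", seq_len(2L * n_per_class)),
      class = rep(c("enriched", "background"), each = n_per_class),
      bases = c(mk(n_per_class, base_rate * enrichment, "e"),
                mk(n_per_class, base_rate, "b"))
    )
  })
}
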