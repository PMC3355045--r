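# Tiling-array signal analytics: per-gene binding values from exon probes,
# peak/region calling with the 3-SD / 360-bp / five-probe rules, dual-antibody
# intersection, TSS-to-peak distances, binned co-localization profiles and
# genome coverage.
#
# A probe track is a tibble with columns `chrom`, `pos` (0-based probe
# midpoint, strictly increasing within a chromosome) and `value` (log2
# enrichment ratio).

check_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("chrom", "pos", "value") %in% names(track)))
  if (!nrow(track)) abort("empty probe track", class = "mslseq_input_error")
  bad <- track |>
    group_by(.data$chrom) |>
    summarise(ok = !is.unsorted(.data$pos, strictly = TRUE), .groups = "drop")
  if (!all(bad$ok)) abort("probe positions must be strictly increasing per chromosome",
                          class = "mslseq_input_error")
  invisible(track)
}

#' Gene binding value from exon probe values
#'
#' The mean of the top 50% of a gene's exon probe values (log2 ratios); the
#' upper half minimizes the influence of alternative splicing. Odd counts
#' keep `ceiling(n/2)` probes.
#'
#' @param values Numeric probe values over all exons of one gene.
#' @return The binding value, or `NA` for an empty vector (gene excluded).
#' @examples
#' gene_binding_value(c(1, 2, 3, 4))  # 3.5
#' @export
gene_binding_value <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  keep <- ceiling(length(values) / 2)
  mean(sort(values, decreasing = TRUE)[seq_len(keep)])
}

#' Gene binding values for every gene and protein track
#'
#' @param tracks Named list of probe tracks (one per protein), or one track.
#' @param genes Gene models from [parse_annotation()] (needs `gene_id`,
#'   `chrom` and the `exons` list-column).
#' @return Tibble `gene_id`, `protein`, `binding_value` (NA when a gene has
#'   no exon probe).
#' @export
gene_binding_table <- function(tracks, genes) {
  if (is.data.frame(tracks)) tracks <- list(signal = tracks)
  stopifnot(!is.null(names(tracks)))
  purrr::imap(tracks, function(track, protein) {
    check_track(track)
    vals <- vapply(seq_len(nrow(genes)), function(i) {
      ex <- genes$exons[[i]]
      tr <- track[track$chrom == genes$chrom[i], ]
      inside <- rep(FALSE, nrow(tr))
      for (j in seq_len(nrow(ex))) {
        inside <- inside | (tr$pos >= ex[j, 1L] & tr$pos < ex[j, 2L])
      }
      gene_binding_value(tr$value[inside])
    }, 0)
    tibble(gene_id = genes$gene_id, protein = protein, binding_value = vals)
  }) |> bind_rows()
}

# value and center from the highest `k` consecutive probes (leftmost tie wins)
best_window <- function(pos, val, k = 6L) {
  n <- length(val)
  k <- min(k, n)
  means <- vapply(seq_len(n - k + 1L), function(i) mean(val[i:(i + k - 1L)]), 0)
  i <- which.max(means)   # ties -> leftmost
  list(value = means[i], center = floor((pos[i] + pos[i + k - 1L]) / 2))
}

#' Call binding regions from a probe track
#'
#' Probes exceeding the genomic average by `sd_mult` standard deviations are
#' chained while consecutive qualifying probes are at most `max_gap` apart;
#' chains spanning less than `min_span` bp or holding fewer than `min_probes`
#' probes are dropped. Each region's value is the mean of its highest six
#' consecutive probe values and its center the mid-position of those probes
#' (all probes when a region has only five).
#'
#' @param track Probe track tibble (`chrom`, `pos`, `value`); the genomic
#'   mean/SD are computed over all probes of all chromosomes.
#' @param sd_mult,min_span,max_gap,min_probes The calling thresholds
#'   (defaults 3, 360, 360, 5).
#' @param stats Optional list `mean`, `sd` overriding the genomic statistics.
#' @return Tibble of regions: `chrom`, `start`, `end` (0-based half-open,
#'   spanning first to last qualifying probe), `value`, `center`, `n_probes`.
#' @export
call_regions <- function(track, sd_mult = 3, min_span = 360, max_gap = 360,
                         min_probes = 5, stats = NULL) {
  check_track(track)
  mu <- stats$mean %||% mean(track$value)
  sdv <- stats$sd %||% sd(track$value)
  thr <- mu + sd_mult * sdv
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    q <- which(tr$value >= thr)
    if (!length(q)) next
    brk <- c(0L, which(diff(tr$pos[q]) > max_gap), length(q))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- q[(brk[b] + 1L):brk[b + 1L]]
      if (length(idx) < min_probes) next
      span <- tr$pos[idx[length(idx)]] - tr$pos[idx[1L]]
      if (span < min_span) next
      bw <- best_window(tr$pos[idx], tr$value[idx], 6L)
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = tr$pos[idx[1L]], end = tr$pos[idx[length(idx)]] + 1L,
        value = bw$value, center = bw$center, n_probes = length(idx)
      )
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric(), center = numeric(), n_probes = integer()))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Intersect two region sets (dual-antibody confirmation)
#'
#' Keeps region pairs overlapping by at least one base; each emitted region is
#' the union span with the larger of the two values and the mean of the two
#' centers.
#'
#' @param regions_a,regions_b Region tibbles from [call_regions()].
#' @return Region tibble of confirmed regions.
#' @export
intersect_regions <- function(regions_a, regions_b) {
  out <- list()
  for (ch in intersect(unique(regions_a$chrom), unique(regions_b$chrom))) {
    a <- regions_a[regions_a$chrom == ch, ]
    b <- regions_b[regions_b$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      hit <- which(b$start < a$end[i] & b$end > a$start[i])
      for (j in hit) {
        out[[length(out) + 1L]] <- tibble(
          chrom = ch,
          start = min(a$start[i], b$start[j]), end = max(a$end[i], b$end[j]),
          value = max(a$value[i], b$value[j]),
          center = (a$center[i] + b$center[j]) / 2,
          n_probes = a$n_probes[i] + b$n_probes[j]
        )
      }
    }
  }
  if (!length(out)) {
    return(regions_a[0, ])
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Distance from each TSS to the nearest peak center
#'
#' @param genes Gene models tibble (`gene_id`, `chrom`, `tss`).
#' @param peaks Region tibble with `chrom`, `center`.
#' @return Tibble `gene_id`, `chrom`, `tss`, `distance` (NA on peak-free
#'   chromosomes).
#' @export
tss_peak_distance <- function(genes, peaks) {
  dist <- vapply(seq_len(nrow(genes)), function(i) {
    ctr <- peaks$center[peaks$chrom == genes$chrom[i]]
    if (!length(ctr)) return(NA_real_)
    min(abs(genes$tss[i] - ctr))
  }, 0)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom, tss = genes$tss,
         distance = dist)
}

#' Average signal in fixed bins around anchor centers
#'
#' Probe values are assigned to `bin`-bp bins by signed distance from each
#' anchor's center; anchors whose gene points leftward (`strand == "-"`) are
#' mirrored so the TSS always lies to the right. Returns the per-bin mean over
#' all anchors.
#'
#' @param track Probe track tibble.
#' @param anchors Tibble with `chrom`, `center` and optionally `strand`
#'   (`+`/`-`; `-` mirrors the profile).
#' @param bin Bin width in bp (default 100).
#' @param span Total profile width in bp (a multiple of `bin`).
#' @return Tibble `bin_start`, `bin_mid`, `mean_value`, `n_probes`; bins with
#'   no probes are absent.
#' @export
binned_colocalization <- function(track, anchors, bin = 100, span = 2000) {
  check_track(track)
  if (span %% bin != 0) abort("`span` must be a multiple of `bin`",
                              class = "mslseq_parameter_error")
  half <- span / 2
  strand <- anchors$strand %||% rep("+", nrow(anchors))
  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    tr <- track[track$chrom == anchors$chrom[i], ]
    d <- tr$pos - anchors$center[i]
    if (strand[i] == "-") d <- -d
    keep <- d >= -half & d < half
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- tibble(d = d[keep], value = tr$value[keep])
  }
  if (!length(rows)) {
    warn("no probes within `span` of any anchor")
    return(tibble(bin_start = numeric(), bin_mid = numeric(),
                  mean_value = numeric(), n_probes = integer()))
  }
  bind_rows(rows) |>
    mutate(bin_start = floor(.data$d / bin) * bin) |>
    group_by(.data$bin_start) |>
    summarise(mean_value = mean(.data$value), n_probes = dplyr::n(),
              .groups = "drop") |>
    mutate(bin_mid = .data$bin_start + bin / 2) |>
    select("bin_start", "bin_mid", "mean_value", "n_probes") |>
    arrange(.data$bin_start)
}

#' Fraction of each chromosome covered by regions
#'
#' @param regions Sorted, non-overlapping region tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return Tibble `chrom`, `covered_bp`, `length`, `fraction` (chromosomes
#'   without regions report 0).
#' @export
coverage_fraction <- function(regions, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  if (nrow(regions)) {
    bad <- !regions$chrom %in% names(chrom_lengths) |
      regions$end > chrom_lengths[regions$chrom]
    if (any(bad)) abort("region outside chromosome bounds",
                        class = "mslseq_validation_error")
  }
  cov <- regions |>
    group_by(.data$chrom) |>
    summarise(covered_bp = sum(.data$end - .data$start), .groups = "drop")
  tibble(chrom = names(chrom_lengths),
         length = as.numeric(chrom_lengths)) |>
    left_join(cov, by = "chrom") |>
    mutate(covered_bp = dplyr::coalesce(.data$covered_bp, 0),
           fraction = .data$covered_bp / .data$length) |>
    select("chrom", "covered_bp", "length", "fraction")
}

#' Read and write probe tracks as bedGraph
#'
#' bedGraph intervals are 0-based half-open; probe positions are taken as the
#' interval midpoints (floored).
#'
#' @param path bedGraph file.
#' @return `read_bedgraph()`: a probe-track tibble.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2),
    value = gr$score
  ) |> arrange(.data$chrom, .data$pos)
}

#' @rdname read_bedgraph
#' @param track Probe-track tibble.
#' @param probe_width Width in bp of the emitted interval per probe.
#' @export
write_bedgraph <- function(track, path, probe_width = 1) {
  check_track(track)
  half <- floor(probe_width / 2)
  df <- data.frame(chrom = track$chrom,
                   start = as.integer(track$pos - half),
                   end = as.integer(track$pos - half + probe_width),
                   value = sprintf("%.6g", track$value))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write called regions as BED6
#'
#' @param regions Region tibble.
#' @param path Output BED file; score is the region value scaled by 100 and
#'   rounded.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(
    chrom = regions$chrom, start = as.integer(regions$start),
    end = as.integer(regions$end),
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = as.integer(round(regions$value * 100)), strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
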