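# Genome + annotation parsing and derivation of the six non-overlapping
# gene-feature classes: promoter (up to 500 bp upstream of the TSS, truncated
# at neighbouring genes/promoters), 5' UTR, CDS, intron, 3' UTR and
# intergenic. Internal coordinates are 0-based half-open; GFF3 at the
# boundary is 1-based inclusive.

iv_sort <- function(m) {
  if (!nrow(m)) return(m)
  m[order(m[, 1L]), , drop = FALSE]
}

iv_from_ranges <- function(r) {
  cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

ranges_from_iv <- function(m) {
  IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L])
}

empty_iv <- function() cbind(start = integer(), end = integer())

#' Parse a GFF3 annotation into gene models
#'
#' Reads gene/mRNA/exon/CDS records, keeps the longest transcript per gene
#' (largest summed exon length), and derives UTRs (exon minus CDS, split by
#' side of the CDS) and introns. Coordinates are converted to 0-based
#' half-open.
#'
#' @param gff Path to a GFF3 file, or GFF3 text (contains a newline).
#' @return Tibble of gene models: `gene_id`, `chrom`, `strand`, `tss` (0-based
#'   coordinate of the first transcribed base), `span_start`, `span_end`, and
#'   list-columns `exons`, `cds`, `utr5`, `utr3`, `introns` of sorted
#'   non-overlapping `[start, end)` interval matrices.
#' @export
parse_annotation <- function(gff) {
  path <- gff
  if (length(gff) == 1L && grepl("\n", gff, fixed = TRUE)) {
    path <- tempfile(fileext = ".gff3")
    writeLines(gff, path)
    on.exit(unlink(path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("GFF3 parse error: ", conditionMessage(e)),
                              class = "mslseq_parse_error")
  )
  first_parent <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  genes <- gr[gr$type == "gene"]
  mrnas <- gr[gr$type == "mRNA"]
  parts <- gr[gr$type %in% c("exon", "CDS")]
  part_parent <- first_parent(parts)
  mrna_gene <- first_parent(mrnas)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    tx_ids <- mrnas$ID[mrna_gene == gid]
    if (!length(tx_ids)) tx_ids <- gid   # parts may point straight at the gene
    # longest transcript: largest summed exon width
    exon_of <- function(tx) parts[parts$type == "exon" & part_parent == tx]
    widths <- vapply(tx_ids, function(tx) sum(IRanges::width(exon_of(tx))), 0)
    tx <- tx_ids[which.max(widths)]
    ex <- exon_of(tx)
    cd <- parts[parts$type == "CDS" & part_parent == tx]
    if (!length(ex) && length(cd)) ex <- cd
    if (!length(ex)) ex <- genes[i]
    exm <- iv_sort(iv_from_ranges(IRanges::reduce(IRanges::ranges(ex))))
    cdm <- if (length(cd)) {
      iv_sort(iv_from_ranges(IRanges::reduce(IRanges::ranges(cd))))
    } else empty_iv()
    if (nrow(cdm)) {
      outside <- IRanges::setdiff(ranges_from_iv(cdm), ranges_from_iv(exm))
      if (length(outside)) {
        abort(sprintf("gene %s: CDS outside exons", gid),
              class = "mslseq_validation_error")
      }
    }
    strand <- as.character(BiocGenerics::strand(genes[i]))
    if (!strand %in% c("+", "-")) strand <- "+"
    span <- c(min(exm[, 1L]), max(exm[, 2L]))
    tss <- if (strand == "+") span[1L] else span[2L] - 1L
    # UTRs: exon bases outside the CDS span, split by side
    if (nrow(cdm)) {
      cspan <- c(min(cdm[, 1L]), max(cdm[, 2L]))
      exr <- ranges_from_iv(exm)
      left <- IRanges::intersect(exr, IRanges::IRanges(span[1L] + 1L, cspan[1L]))
      right <- IRanges::intersect(exr, IRanges::IRanges(cspan[2L] + 1L, span[2L]))
      leftm <- iv_from_ranges(left); rightm <- iv_from_ranges(right)
      if (strand == "+") { u5 <- leftm; u3 <- rightm } else { u5 <- rightm; u3 <- leftm }
    } else {
      u5 <- empty_iv(); u3 <- empty_iv()
    }
    gaps <- IRanges::gaps(ranges_from_iv(exm),
                          start = span[1L] + 1L, end = span[2L])
    out[[i]] <- tibble(
      gene_id = gid, chrom = as.character(GenomicRanges::seqnames(genes[i])),
      strand = strand, tss = tss,
      span_start = span[1L], span_end = span[2L],
      exons = list(exm), cds = list(cdm),
      utr5 = list(u5), utr3 = list(u3),
      introns = list(iv_from_ranges(gaps))
    )
  }
  bind_rows(out)
}

# keep the piece of an interval set adjacent to a boundary after subtraction
adjacent_piece <- function(candidate, covered, at_end) {
  un <- IRanges::setdiff(ranges_from_iv(candidate), covered)
  if (!length(un)) return(NULL)
  m <- iv_from_ranges(un)
  if (at_end) {
    piece <- m[nrow(m), , drop = FALSE]
    if (piece[, 2L] != candidate[, 2L]) return(NULL)
  } else {
    piece <- m[1L, , drop = FALSE]
    if (piece[, 1L] != candidate[, 1L]) return(NULL)
  }
  piece
}

#' Derive the six gene-feature coordinate classes
#'
#' Promoters extend up to 500 bp upstream of the TSS, truncated where they
#' overlap another gene body; promoters overlapping each other are clipped at
#' the midpoint of their mutual overlap; genes whose entire upstream region
#' lies inside a neighbouring gene are flagged excluded (returned in the
#' `excluded_genes` attribute, with no promoter interval). Intergenic is the
#' per-chromosome complement of gene spans and promoters. Within a gene,
#' precedence CDS > UTR > intron resolves any annotation conflicts.
#'
#' @param genes Gene models from [parse_annotation()].
#' @param chrom_lengths Named vector of chromosome lengths covering all
#'   chromosomes present.
#' @param promoter_bp Promoter length upstream of the TSS (default 500).
#' @return Tibble of feature coordinates: `owner_gene`, `feature_class`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open), with attribute
#'   `excluded_genes`.
#' @export
derive_features <- function(genes, chrom_lengths, promoter_bp = 500) {
  stopifnot(all(genes$chrom %in% names(chrom_lengths)))
  if (any(genes$span_end > chrom_lengths[genes$chrom])) {
    abort("gene beyond chromosome length", class = "mslseq_validation_error")
  }
  n <- nrow(genes)
  # candidate promoters
  prom <- matrix(NA_integer_, n, 2L)
  for (i in seq_len(n)) {
    len <- chrom_lengths[[genes$chrom[i]]]
    if (genes$strand[i] == "+") {
      prom[i, ] <- c(max(0L, genes$span_start[i] - promoter_bp), genes$span_start[i])
    } else {
      prom[i, ] <- c(genes$span_end[i], min(len, genes$span_end[i] + promoter_bp))
    }
  }
  excluded <- rep(FALSE, n)
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i] & seq_len(n) != i)
    covered <- ranges_from_iv(cbind(genes$span_start[same], genes$span_end[same]))
    piece <- adjacent_piece(prom[i, , drop = FALSE], covered,
                            at_end = genes$strand[i] == "+")
    if (is.null(piece) || piece[, 2L] <= piece[, 1L]) {
      excluded[i] <- TRUE
    } else {
      kept[[i]] <- piece
    }
  }
  # promoter-promoter overlaps: clip both at the overlap midpoint
  for (i in seq_len(n)) {
    if (excluded[i]) next
    for (j in seq_len(n)) {
      if (j <= i || excluded[j] || genes$chrom[i] != genes$chrom[j]) next
      a <- kept[[i]]; b <- kept[[j]]
      if (is.null(a) || is.null(b)) next
      lo <- max(a[1L], b[1L]); hi <- min(a[2L], b[2L])
      if (lo >= hi) next
      mid <- (lo + hi) %/% 2L
      if (a[1L] < b[1L]) { a[2L] <- min(a[2L], mid); b[1L] <- max(b[1L], mid) }
      else               { b[2L] <- min(b[2L], mid); a[1L] <- max(a[1L], mid) }
      kept[[i]] <- a; kept[[j]] <- b
      if (a[2L] <= a[1L]) excluded[i] <- TRUE
      if (b[2L] <= b[1L]) excluded[j] <- TRUE
    }
  }
  rows <- list()
  add <- function(owner, class, chrom, m, strand) {
    if (is.null(m) || !nrow(m)) return()
    keep <- m[, 2L] > m[, 1L]
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) return()
    rows[[length(rows) + 1L]] <<- tibble(
      owner_gene = owner, feature_class = class, chrom = chrom,
      start = as.integer(m[, 1L]), end = as.integer(m[, 2L]), strand = strand
    )
  }
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (!excluded[i]) add(g$gene_id, "promoter", g$chrom, kept[[i]], g$strand)
    cds <- g$cds[[1L]]
    higher <- ranges_from_iv(cds)
    utr5 <- iv_from_ranges(IRanges::setdiff(ranges_from_iv(g$utr5[[1L]]), higher))
    utr3 <- iv_from_ranges(IRanges::setdiff(ranges_from_iv(g$utr3[[1L]]), higher))
    higher <- IRanges::union(higher, ranges_from_iv(rbind(utr5, utr3)))
    introns <- iv_from_ranges(IRanges::setdiff(ranges_from_iv(g$introns[[1L]]), higher))
    add(g$gene_id, "cds", g$chrom, cds, g$strand)
    add(g$gene_id, "utr5", g$chrom, utr5, g$strand)
    add(g$gene_id, "utr3", g$chrom, utr3, g$strand)
    add(g$gene_id, "intron", g$chrom, introns, g$strand)
  }
  feats <- bind_rows(rows)
  # intergenic: complement of gene spans and kept promoters per chromosome
  for (ch in names(chrom_lengths)) {
    idx <- which(genes$chrom == ch)
    occ <- cbind(genes$span_start[idx], genes$span_end[idx])
    proms <- do.call(rbind, kept[idx[!excluded[idx]]])
    occ <- rbind(occ, proms)
    occr <- IRanges::reduce(ranges_from_iv(occ))
    inter <- IRanges::gaps(occr, start = 1L, end = chrom_lengths[[ch]])
    m <- iv_from_ranges(inter)
    if (nrow(m)) {
      feats <- bind_rows(feats, tibble(
        owner_gene = "intergenic", feature_class = "intergenic", chrom = ch,
        start = as.integer(m[, 1L]), end = as.integer(m[, 2L]), strand = "."
      ))
    }
  }
  feats <- arrange(feats, .data$chrom, .data$start, .data$feature_class)
  attr(feats, "excluded_genes") <- genes$gene_id[excluded]
  feats
}

#' Extract feature sequences from a genome
#'
#' CDS, UTR, intron and promoter sequences are reported on the coding strand
#' (reverse-complemented for minus-strand genes), so promoters read 5' to 3'
#' toward the TSS; intergenic sequences stay on the forward strand. Bases are
#' uppercased.
#'
#' @param coords Feature coordinate tibble from [derive_features()].
#' @param genome A `DNAStringSet` (names = chromosomes) or FASTA path.
#' @return `coords` with a `bases` column added.
#' @export
extract_sequences <- function(coords, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(coords$chrom), names(genome))
  if (length(missing)) {
    abort(paste0("chromosome(s) missing from FASTA: ",
                 paste(missing, collapse = ", ")), class = "mslseq_lookup_error")
  }
  bases <- character(nrow(coords))
  for (ch in unique(coords$chrom)) {
    idx <- which(coords$chrom == ch)
    ss <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(coords$start[idx] + 1L, coords$end[idx])
    )
    s <- toupper(as.character(ss))
    flip <- coords$strand[idx] == "-"
    if (any(flip)) s[flip] <- revcomp(s[flip])
    bases[idx] <- s
  }
  coords$bases <- bases
  coords
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` or FASTA path.
#' @return Named integer vector.
#' @export
chrom_lengths_of <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  setNames(Biostrings::width(genome), names(genome))
}

#' Write derived feature coordinates as BED6
#'
#' @param coords Feature coordinate tibble.
#' @param path Output path.
#' @export
write_features_bed <- function(coords, path) {
  df <- data.frame(
    chrom = coords$chrom, start = coords$start, end = coords$end,
    name = paste(coords$owner_gene, coords$feature_class, sep = "|"),
    score = 0L, strand = ifelse(coords$strand %in% c("+", "-"), coords$strand, ".")
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
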