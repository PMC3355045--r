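test_that("annotation parsing derives strand-aware gene models", {
  genes <- parse_annotation(tiny_gff())
  expect_equal(nrow(genes), 3L)
  gA <- genes[genes$gene_id == "gA", ]
  expect_equal(gA$tss, 2000)            # 1-based 2001 -> 0-based 2000
  expect_equal(gA$exons[[1]],
               cbind(start = c(2000L, 2600L), end = c(2400L, 3000L)),
               ignore_attr = TRUE)
  expect_equal(unname(gA$utr5[[1]][, 2] - gA$utr5[[1]][, 1]), 100L)  # 2001..2100
  expect_equal(gA$introns[[1]], cbind(2400L, 2600L), ignore_attr = TRUE)
  # minus strand: TSS is the 3'-most base of the span
  gB <- genes[genes$gene_id == "gB", ]
  expect_equal(gB$tss, 5999)
  expect_equal(gB$utr5[[1]], cbind(5900L, 6000L), ignore_attr = TRUE)
  # single-exon non-coding gene: no CDS, no introns
  gC <- genes[genes$gene_id == "gC", ]
  expect_equal(nrow(gC$cds[[1]]), 0L)
  expect_equal(nrow(gC$introns[[1]]), 0L)
})

test_that("CDS outside exons and malformed input are rejected", {
  bad <- paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t100\t300\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\ttest\tCDS\t250\t450\t.\t+\t0\tID=c1;Parent=g1.t1",
    sep = "\n")
  expect_error(parse_annotation(bad), class = "mslseq_validation_error")
  expect_error(parse_annotation("not\tgff\nat all"),
               class = "mslseq_parse_error")
})

test_that("promoters extend 500 bp and are truncated by neighbours", {
  lens <- c(chr1 = 10000, chr2 = 1000)
  feats <- derive_features(parse_annotation(tiny_gff()), lens)
  prom <- feats[feats$feature_class == "promoter", ]
  pA <- prom[prom$owner_gene == "gA", ]
  expect_equal(pA$end - pA$start, 500L)       # isolated: full 500
  expect_equal(c(pA$start, pA$end), c(1500L, 2000L))
  # gB is minus strand at [5000,6000): promoter on its right
  pB <- prom[prom$owner_gene == "gB", ]
  expect_equal(c(pB$start, pB$end), c(6000L, 6500L))
  # gC starts 100 bp into chr2: promoter clipped at the chromosome edge
  pC <- prom[prom$owner_gene == "gC", ]
  expect_equal(pC$end - pC$start, 100L)

  # head-to-tail genes 300 bp apart: downstream promoter truncated to 300
  gff2 <- paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=u1",
    "chr1\ttest\tmRNA\t1001\t2000\t.\t+\t.\tID=u1.t;Parent=u1",
    "chr1\ttest\texon\t1001\t2000\t.\t+\t.\tID=u1.e;Parent=u1.t",
    "chr1\ttest\tgene\t2301\t3300\t.\t+\t.\tID=d1",
    "chr1\ttest\tmRNA\t2301\t3300\t.\t+\t.\tID=d1.t;Parent=d1",
    "chr1\ttest\texon\t2301\t3300\t.\t+\t.\tID=d1.e;Parent=d1.t",
    sep = "\n")
  f2 <- derive_features(parse_annotation(gff2), c(chr1 = 5000))
  p_d1 <- f2[f2$feature_class == "promoter" & f2$owner_gene == "d1", ]
  expect_equal(p_d1$end - p_d1$start, 300L)
  expect_equal(c(p_d1$start, p_d1$end), c(2000L, 2300L))
})

test_that("a promoter fully inside a neighbour flags the gene excluded", {
  gff3 <- paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t4000\t.\t+\t.\tID=host",
    "chr1\ttest\tmRNA\t1001\t4000\t.\t+\t.\tID=host.t;Parent=host",
    "chr1\ttest\texon\t1001\t4000\t.\t+\t.\tID=host.e;Parent=host.t",
    "chr1\ttest\tgene\t2001\t3000\t.\t+\t.\tID=nested",
    "chr1\ttest\tmRNA\t2001\t3000\t.\t+\t.\tID=nested.t;Parent=nested",
    "chr1\ttest\texon\t2001\t3000\t.\t+\t.\tID=nested.e;Parent=nested.t",
    sep = "\n")
  f3 <- derive_features(parse_annotation(gff3), c(chr1 = 10000))
  expect_true("nested" %in% attr(f3, "excluded_genes"))
  expect_false(any(f3$feature_class == "promoter" &
                     f3$owner_gene == "nested"))
})

test_that("derived feature classes never overlap and promoters stay in (0,500]", {
  ds <- generate_dataset(synth_config(n_genes_per_class = 10, seed = 3))
  d <- withr::local_tempdir()
  paths <- write_dataset(ds, d)
  genes <- parse_annotation(paths[["annotation"]])
  lens <- chrom_lengths_of(paths[["genome"]])
  feats <- derive_features(genes, lens)
  for (ch in unique(feats$chrom)) {
    f <- feats[feats$chrom == ch, ]
    f <- f[order(f$start), ]
    expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  }
  prom <- feats[feats$feature_class == "promoter", ]
  expect_true(all(prom$end - prom$start > 0 & prom$end - prom$start <= 500))
  # round trip: parsed coordinates match the generator's truth exactly
  tg <- ds$truth$genes
  m <- match(tg$gene_id, genes$gene_id)
  expect_equal(genes$tss[m], tg$tss)
  expect_equal(genes$span_start[m], tg$span_start)
  expect_equal(genes$span_end[m], tg$span_end)
})

test_that("sequences are extracted on the coding strand and uppercased", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ttttttttttACGTACtttttttttt"))
  coords <- tibble::tibble(owner_gene = "g", feature_class = "cds",
                           chrom = "chr1", start = 10L, end = 16L,
                           strand = c("+"))
  expect_equal(extract_sequences(coords, genome)$bases, "ACGTAC")
  coords$strand <- "-"
  expect_equal(extract_sequences(coords, genome)$bases, "GTACGT")
  coords$chrom <- "chrX"
  expect_error(extract_sequences(coords, genome),
               class = "mslseq_lookup_error")
})

test_that("feature sequence totals per class match the truth intervals", {
  ds <- generate_dataset(synth_config(n_genes_per_class = 8, seed = 13))
  d <- withr::local_tempdir()
  paths <- write_dataset(ds, d)
  genes <- parse_annotation(paths[["annotation"]])
  feats <- extract_sequences(derive_features(genes, chrom_lengths_of(paths[["genome"]])),
                             paths[["genome"]])
  got_cds <- sum(nchar(feats$bases[feats$feature_class == "cds"]))
  want_cds <- sum(vapply(ds$truth$genes$cds, function(m) sum(m[, 2] - m[, 1]), 0))
  expect_equal(got_cds, want_cds)
  expect_true(all(nchar(feats$bases) == feats$end - feats$start))
})
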