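test_that("gene binding value is the mean of the top half of probes", {
  expect_equal(gene_binding_value(c(1, 2, 3, 4)), 3.5)
  expect_equal(gene_binding_value(c(1, 2, 3)), 2.5)   # ceiling(3/2) = 2 kept
  expect_equal(gene_binding_value(5), 5)
  expect_true(is.na(gene_binding_value(numeric())))
  # monotone: raising any probe never lowers the value
  v <- c(0.2, 1.4, 0.8, 2.1, 0.5)
  for (i in seq_along(v)) {
    up <- v; up[i] <- up[i] + 1
    expect_gte(gene_binding_value(up), gene_binding_value(v))
  }
})

test_that("region calling applies the span, gap and probe-count rules", {
  # flat background plus 8 consecutive high probes, 100 bp spacing
  pos <- seq(100, 10000, by = 100)
  val <- rep(0, length(pos))
  withr::with_seed(2, val <- rnorm(length(pos), 0, 0.01))
  hi <- 41:48
  val[hi] <- 10
  tr <- toy_track(pos, val)
  reg <- call_regions(tr)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, pos[41])
  expect_equal(reg$end, pos[48] + 1L)
  expect_equal(reg$end - 1L - reg$start, 700L)   # spans first to last probe
  expect_equal(reg$value, 10, tolerance = 1e-9)
  # all windows tie: the leftmost six qualifying probes define the center
  expect_equal(reg$center, floor((pos[41] + pos[46]) / 2))
  expect_equal(reg$n_probes, 8L)

  # four consecutive high probes fail the five-probe rule
  val4 <- val; val4[hi] <- 0; val4[41:44] <- 10
  expect_equal(nrow(call_regions(toy_track(pos, val4))), 0L)
  # five high probes spanning 400 bp pass and use all five
  val5 <- val; val5[hi] <- 0; val5[41:45] <- c(5, 6, 9, 6, 5)
  reg5 <- call_regions(toy_track(pos, val5))
  expect_equal(reg5$n_probes, 5L)
  expect_equal(reg5$value, mean(c(5, 6, 9, 6, 5)))
  expect_error(call_regions(toy_track(integer(), numeric())),
               class = "mslseq_input_error")
})

test_that("a gap wider than max_gap splits a region", {
  pos <- c(seq(100, 600, 100), seq(1100, 1600, 100))
  tr <- toy_track(c(pos, seq(5000, 50000, 100)),
                  c(rep(10, 12), rep(0, 451)))
  reg <- call_regions(tr, stats = list(mean = 0, sd = 0.5))
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(100L, 1100L))
})

test_that("dual-antibody intersection keeps overlapping pairs as union spans", {
  a <- tibble::tibble(chrom = "chr1", start = 100L, end = 600L, value = 2,
                      center = 350, n_probes = 6L)
  b <- tibble::tibble(chrom = "chr1", start = 500L, end = 900L, value = 3,
                      center = 700, n_probes = 6L)
  out <- intersect_regions(a, b)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 900L)
  expect_equal(out$value, 3)
  expect_equal(out$center, 525)
  expect_equal(intersect_regions(a, a), a |> dplyr::mutate(
    center = as.numeric(center), n_probes = 2L * n_probes),
    ignore_attr = TRUE)
  disjoint <- b |> dplyr::mutate(start = 2000L, end = 2400L)
  expect_equal(nrow(intersect_regions(a, disjoint)), 0L)
})

test_that("TSS distances use the nearest same-chromosome peak center", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          chrom = c("chr1", "chr1", "chr2"),
                          tss = c(1000, 800, 50))
  peaks <- tibble::tibble(chrom = "chr1", center = c(800, 1500))
  d <- tss_peak_distance(genes, peaks)
  expect_equal(d$distance, c(200, 0, NA))
})

test_that("co-localization bins are signed, mirrored and averaged", {
  tr <- toy_track(c(850, 1050), c(2, 4))
  anchors <- tibble::tibble(chrom = "chr1", center = 1000, strand = "+")
  prof <- binned_colocalization(tr, anchors, bin = 100, span = 400)
  expect_equal(prof$bin_start, c(-200, 0))
  expect_equal(prof$mean_value, c(2, 4))
  # a minus-strand anchor mirrors +50 into the [-100, 0) bin
  anchors$strand <- "-"
  prof2 <- binned_colocalization(tr, anchors, bin = 100, span = 400)
  expect_equal(prof2$bin_start, c(-100, 100))
  expect_equal(prof2$mean_value, c(4, 2))
  expect_error(binned_colocalization(tr, anchors, bin = 100, span = 450),
               class = "mslseq_parameter_error")
  far <- tibble::tibble(chrom = "chr1", center = 10000, strand = "+")
  expect_warning(empty <- binned_colocalization(tr, far, 100, 400))
  expect_equal(nrow(empty), 0L)
})

test_that("coverage fractions are per chromosome and bounds-checked", {
  reg <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L,
                        value = 1, center = 200, n_probes = 5L)
  cov <- coverage_fraction(reg, c(chr1 = 10000, chr2 = 5000))
  expect_equal(cov$fraction, c(0.02, 0))
  expect_error(coverage_fraction(reg |> dplyr::mutate(end = 20000L),
                                 c(chr1 = 10000)),
               class = "mslseq_validation_error")
})

test_that("planted promoter peaks separate strong from weak TSS distances", {
  # 30 strong genes with a peak 150 bp upstream, 30 weak genes without,
  # alternating every 10 kb along one chromosome
  tss <- seq(20000, 20000 + 59 * 10000, by = 10000)
  cls <- rep(c("strong", "weak"), 30)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:60), chrom = "chrS",
                          tss = tss)
  withr::with_seed(71, {
    pos <- seq(50, max(tss) + 20000, by = 100)
    val <- rnorm(length(pos), 0, 0.1)
    for (ctr in tss[cls == "strong"] - 150) {
      val <- val + exp(-(pos - ctr)^2 / (2 * 250^2))
    }
  })
  reg <- call_regions(toy_track(pos, val, "chrS"))
  d <- tss_peak_distance(genes, reg)
  mw <- compare_groups(d$distance[cls == "weak"], d$distance[cls == "strong"],
                       "mann_whitney", alternative = "greater")
  expect_lt(mw$p_value, 0.01)
})

test_that("probe tracks round-trip through bedGraph", {
  tr <- toy_track(c(150, 250, 350), c(0.5, -1.25, 2))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path)
  expect_equal(back$pos, tr$pos)
  expect_equal(back$value, tr$value, tolerance = 1e-6)
})
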