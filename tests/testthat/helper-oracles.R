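# Independent oracles and small fixture builders. Everything here is written
# from scratch (no calls into the implementation paths being tested).

# brute-force merged word counting: enumerate every window into a dictionary,
# then merge reverse complements (independent of Biostrings)
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_count_words <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer())
  wins <- substring(seq, 1:(n - k + 1), k:n)
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins)) return(integer())
  rc <- oracle_revcomp(wins)
  canon <- ifelse(wins <= rc, wins, rc)
  tab <- table(canon)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# single-component PLS (NIPALS, one pass on centered data): the reference for
# OPLS-DA with zero orthogonal components
oracle_pls1 <- function(X, y) {
  y <- y - mean(y)
  w <- drop(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  t_ <- drop(X %*% w)
  if (cor(t_, y) < 0) { w <- -w; t_ <- -t_ }
  list(w = w, scores = t_)
}

# scaled gaussian matrix with dimnames
scaled_random_matrix <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("o%02d", 1:n), sprintf("v%03d", 1:p)))
  })
  scale(m)
}

# random DNA with given AT fraction
rand_seq <- function(n, at = 0.6) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# promoters with a PWM planted at a given probability (the recovery fixture)
planted_promoters <- function(n, insert_prob, pwm, len = 500,
                              base_probs = c(0.3, 0.2, 0.2, 0.3)) {
  vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = base_probs), collapse = "")
    if (runif(1) < insert_prob) {
      s <- plant_motif(s, pwm, sample.int(len - nrow(as.matrix(pwm)), 1) - 1L)
    }
    s
  }, "")
}

# a small three-gene GFF3 (plus/minus strand, single-exon non-coding)
tiny_gff <- function() {
  paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t2001\t3000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t2001\t3000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttest\texon\t2001\t2400\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "chr1\ttest\texon\t2601\t3000\t.\t+\t.\tID=gA.t1.e2;Parent=gA.t1",
    "chr1\ttest\tCDS\t2101\t2400\t.\t+\t0\tID=gA.t1.c1;Parent=gA.t1",
    "chr1\ttest\tCDS\t2601\t2900\t.\t+\t0\tID=gA.t1.c2;Parent=gA.t1",
    "chr1\ttest\tgene\t5001\t6000\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t5001\t6000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttest\texon\t5001\t6000\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1",
    "chr1\ttest\tCDS\t5101\t5900\t.\t-\t0\tID=gB.t1.c1;Parent=gB.t1",
    "chr2\ttest\tgene\t101\t700\t.\t+\t.\tID=gC",
    "chr2\ttest\tmRNA\t101\t700\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr2\ttest\texon\t101\t700\t.\t+\t.\tID=gC.t1.e1;Parent=gC.t1",
    sep = "\n"
  )
}

# probe track from explicit positions/values on one chromosome
toy_track <- function(pos, value, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), value = value)
}
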