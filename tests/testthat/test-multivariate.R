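test_that("PCA matches an independent eigendecomposition", {
  m <- scaled_random_matrix(10, 20, seed = 5)
  fit <- fit_pca(m, 5)
  ev <- eigen(crossprod(m))
  # eigenvalues give the explained variance; vectors match up to sign
  expect_equal(fit$r2cum, cumsum(ev$values[1:5]) / sum(ev$values),
               tolerance = 1e-8)
  for (j in 1:5) {
    v <- ev$vectors[, j]
    expect_equal(abs(sum(fit$loadings[, j] * v)), 1, tolerance = 1e-8)
  }
  # full reconstruction
  full <- fit_pca(m, 9)
  rec <- full$scores %*% t(full$loadings)
  expect_equal(rec, unclass(m), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-1 data are explained by one component", {
  m <- outer(1:6 - 3.5, seq(-1, 1, length.out = 8))
  dimnames(m) <- list(paste0("o", 1:6), paste0("v", 1:8))
  fit <- fit_pca(m, 2)
  expect_equal(fit$r2cum[1], 1, tolerance = 1e-12)
})

test_that("PCA refuses unscaled word matrices", {
  wm <- word_matrix(c(a = strrep("ACGT", 50), b = strrep("AATT", 50)), 2, 2)
  expect_error(fit_pca(wm), class = "mslseq_state_error")
})

test_that("layouts agree in PCA once duplicate columns are weighted once", {
  withr::with_seed(12, seqs <- setNames(replicate(8, rand_seq(1500)),
                                        paste0("s", 1:8)))
  pub <- scale_matrix(at_normalize(word_matrix(seqs, 2, 4, "as_published")),
                      "centered")
  can <- scale_matrix(at_normalize(word_matrix(seqs, 2, 4, "canonical")),
                      "centered")
  # a non-palindromic class appears twice in the published layout; weighting
  # those columns by 1/sqrt(2) makes the two Gram matrices identical
  dup <- colnames(pub) != oracle_revcomp(colnames(pub))
  pub_w <- unclass(pub)
  pub_w[, dup] <- pub_w[, dup] / sqrt(2)
  a <- fit_pca(pub_w, 3)$scores
  b <- fit_pca(unclass(can), 3)$scores
  for (j in 1:3) {
    expect_equal(abs(cor(a[, j], b[, j])), 1, tolerance = 1e-8)
  }
})

test_that("OPLS-DA with no orthogonal component equals single-component PLS", {
  m <- scaled_random_matrix(24, 40, seed = 8)
  labels <- rep(c("strong", "weak"), each = 12)
  fit <- fit_oplsda(m, labels, n_orth = 0, folds = 4, seed = 2)
  ref <- oracle_pls1(unclass(m), ifelse(labels == "strong", 1, -1))
  expect_equal(unname(fit$predictive_weights), unname(ref$w), tolerance = 1e-6)
  expect_equal(fit$training_scores$score, unname(ref$scores), tolerance = 1e-6)
})

test_that("predictive scores are invariant to the orthogonal variance scale", {
  labels <- rep(c("strong", "weak"), each = 20)
  withr::with_seed(31, {
    n <- 40; p <- 60
    t_pred <- rep(c(2, -2), each = n / 2) + rnorm(n, 0, 0.2)
    # orthogonal variation: exactly uncorrelated with the class coding
    y_c <- scale(ifelse(labels == "strong", 1, -1), scale = FALSE)
    t_orth <- rnorm(n, 0, 4)
    t_orth <- drop(t_orth - y_c %*% crossprod(y_c, t_orth) / sum(y_c^2))
    w_pred <- rnorm(p); w_pred <- w_pred / sqrt(sum(w_pred^2))
    w_orth <- rnorm(p)
    w_orth <- w_orth - sum(w_orth * w_pred) * w_pred
    w_orth <- w_orth / sqrt(sum(w_orth^2))
  })
  # exact rank-2 structure: one predictive plus one orthogonal direction
  mk <- function(orth_scale) {
    m <- tcrossprod(t_pred, w_pred) + orth_scale * tcrossprod(t_orth, w_orth)
    dimnames(m) <- list(paste0("o", 1:40), paste0("v", 1:60))
    m
  }
  f1 <- fit_oplsda(mk(1), labels, n_orth = 1, folds = 4, seed = 3)
  f2 <- fit_oplsda(mk(2), labels, n_orth = 1, folds = 4, seed = 3)
  expect_equal(f1$training_scores$score, f2$training_scores$score,
               tolerance = 1e-6)
  # orthogonal training scores are uncorrelated with the labels
  y <- ifelse(labels == "strong", 1, -1)
  t_o <- mk(1) %*% f1$orthogonal_components[[1]]$w
  expect_lt(abs(cor(t_o, y)), 0.2)
})

test_that("prediction reproduces training scores and guards schemas", {
  m <- scaled_random_matrix(20, 30, seed = 4)
  labels <- rep(c("strong", "weak"), each = 10)
  fit <- fit_oplsda(m, labels, n_orth = 1, folds = 4, seed = 9)
  pred <- predict_scores(fit, m, scaled = TRUE)
  expect_equal(pred$score, fit$training_scores$score, tolerance = 1e-10)
  bad <- m[, 1:10]
  expect_error(predict_scores(fit, bad), class = "mslseq_schema_error")
  # an all-zero (scaled) row projects finitely
  z <- m[1:2, , drop = FALSE] * 0
  expect_true(all(is.finite(predict_scores(fit, z, scaled = TRUE)$score)))
})

test_that("Q2 separates signal from permutation null", {
  withr::with_seed(17, {
    m <- rbind(matrix(rnorm(15 * 25, 2), 15), matrix(rnorm(15 * 25, -2), 15))
    dimnames(m) <- list(paste0("o", 1:30), paste0("v", 1:25))
  })
  labels <- rep(c("a", "b"), each = 15)
  expect_gt(cross_validate_q2(scale(m), labels, folds = 5, seed = 1), 0.9)
  # labels independent of (unstructured, high-dimensional) data carry no
  # predictive power
  withr::with_seed(18, {
    m0 <- matrix(rnorm(60 * 200), 60, 200,
                 dimnames = list(paste0("o", 1:60), paste0("v", 1:200)))
  })
  labels0 <- rep(c("a", "b"), each = 30)
  neg <- vapply(1:20, function(s) {
    perm <- withr::with_seed(100 + s, sample(labels0))
    cross_validate_q2(scale(m0), perm, folds = 5, seed = s)
  }, 0)
  expect_gte(sum(neg <= 0), 18)
  expect_error(cross_validate_q2(scale(m), labels, folds = 1),
               class = "mslseq_parameter_error")
  expect_error(cross_validate_q2(scale(m), labels, folds = 20),
               class = "mslseq_parameter_error")
})

test_that("label coding requires two adequately sized classes", {
  m <- scaled_random_matrix(10, 5)
  expect_error(fit_oplsda(m, rep("a", 10)), class = "mslseq_label_error")
  expect_error(fit_oplsda(m, c(rep("a", 8), "b", "b")),
               class = "mslseq_label_error")
})

test_that("random-group null enumerates pairs and stays unpredictive", {
  withr::with_seed(19, seqs <- replicate(80, rand_seq(300)))
  two <- random_group_null(seqs, n_groups = 2, group_size = 30, seed = 1,
                           k_min = 2, k_max = 3, folds = 5)
  expect_equal(nrow(two), 1L)
  expect_error(random_group_null(seqs, n_groups = 7, group_size = 100),
               class = "mslseq_input_error")
})
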