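# PCA and OPLS-DA. PCA is a thin wrapper over the singular value
# decomposition; OPLS-DA is implemented here with the NIPALS orthogonal-
# projection formulation (single predictive component for a binary class,
# orthogonal components removed by iterative deflation), with cross-validated
# Q2 = 1 - PRESS/SS as the predictive-power statistic.

check_scaled <- function(x) {
  if (inherits(x, "word_matrix") && attr(x, "state_scale") == "unscaled") {
    abort("matrix must be scaled before multivariate modeling (see scale_matrix())",
          class = "mslseq_state_error")
  }
  invisible(x)
}

# sign convention shared by PCA and OPLS-DA: the largest-magnitude entry of
# each loading/weight vector is positive, so loading lists are stable
fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v

#' Principal component analysis of a scaled word matrix
#'
#' @param x A scaled `word_matrix` (or plain numeric matrix).
#' @param n_components Number of components to keep (default
#'   `min(nrow - 1, ncol)`).
#' @return A `pca_model` with `scores` (observations x components),
#'   `loadings` (variables x components) and `r2cum`, the cumulative fraction
#'   of variance explained.
#' @export
fit_pca <- function(x, n_components = NULL) {
  check_scaled(x)
  m <- unclass(x)
  amax <- min(nrow(m) - 1L, ncol(m))
  a <- as.integer(n_components %||% amax)
  stopifnot(a >= 1, a <= amax)
  sv <- svd(m, nu = a, nv = a)
  flip <- vapply(seq_len(a), function(j) sv$v[which.max(abs(sv$v[, j])), j] < 0,
                 TRUE)
  sgn <- ifelse(flip, -1, 1)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(a)], a), 2L, sgn, "*")
  loadings <- sweep(sv$v, 2L, sgn, "*")
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(a)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(a)))
  structure(
    list(scores = scores, loadings = loadings,
         r2cum = cumsum(sv$d[seq_len(a)]^2) / sum(sv$d^2),
         sdev = sv$d[seq_len(a)] / sqrt(max(1, nrow(m) - 1L)),
         at = if (inherits(x, "word_matrix")) at_content(x) else NULL),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d observations, %d components; R2cum = %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$r2cum), collapse = ", ")))
  invisible(x)
}

# labels -> y coded +1 (positive class) / -1
code_labels <- function(labels, positive = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2L) {
    abort("exactly two classes are required", class = "mslseq_label_error")
  }
  if (min(table(f)) < 3L) {
    abort("each class needs at least 3 members", class = "mslseq_label_error")
  }
  pos <- positive %||% (if ("strong" %in% levels(f)) "strong" else levels(f)[2L])
  if (!pos %in% levels(f)) abort("`positive` is not a label level",
                                 class = "mslseq_label_error")
  list(y = ifelse(f == pos, 1, -1), positive = pos,
       negative = setdiff(levels(f), pos))
}

# core O-PLS fit on an already-scaled matrix and centered y; returns weights,
# loadings and the regression coefficient of the single predictive component
opls_core <- function(m, y, n_orth) {
  X <- unclass(m)
  orth <- list()
  for (j in seq_len(n_orth)) {
    w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
    t_ <- X %*% w
    p <- crossprod(X, t_) / sum(t_^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- fix_sign(w_o / nw)
    t_o <- X %*% w_o
    p_o <- crossprod(X, t_o) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    orth[[j]] <- list(w = as.numeric(w_o), p = as.numeric(p_o))
  }
  w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
  t_ <- as.numeric(X %*% w)
  ct <- suppressWarnings(cor(t_, y))
  if (!is.na(ct) && ct < 0) { w <- -w; t_ <- -t_ }
  p <- as.numeric(crossprod(X, t_) / sum(t_^2))
  cc <- sum(y * t_) / sum(t_^2)
  list(w = as.numeric(w), p = p, c = cc, orth = orth, t = t_)
}

# project new (already-scaled) data through stored orthogonal components onto
# the predictive component
opls_project <- function(fit, m) {
  X <- unclass(m)
  for (oc in fit$orth) {
    t_o <- X %*% oc$w
    X <- X - tcrossprod(t_o, oc$p)
  }
  as.numeric(X %*% fit$w)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis for a binary class:
#' systematic variation uncorrelated with the class (orthogonal components) is
#' removed by iterative NIPALS deflation before a single predictive component
#' is fit. With `n_orth = "auto"` the number of orthogonal components (0 to
#' `max_orth`) maximizing the cross-validated Q2 is chosen.
#'
#' @param x Scaled `word_matrix` (UV-scaled raw frequencies or centered
#'   AT-normalized ratios) with observations in rows.
#' @param labels Class label per row (exactly two levels).
#' @param n_orth Number of orthogonal components, or `"auto"`.
#' @param positive Label treated as the positive (+1) class; defaults to
#'   `"strong"` when present, otherwise the second factor level.
#' @param folds,seed Cross-validation folds and seed used for Q2 (and for
#'   `n_orth = "auto"` selection).
#' @param max_orth Cap on orthogonal components under `"auto"`.
#' @return An `oplsda_model` with predictive weights/loadings, orthogonal
#'   components, `q2`, training scores and the training column scaling.
#' @export
fit_oplsda <- function(x, labels, n_orth = "auto", positive = NULL,
                       folds = 7, seed = 1, max_orth = 5) {
  check_scaled(x)
  m <- unclass(x)
  stopifnot(nrow(m) == length(labels))
  cl <- code_labels(labels, positive)
  y0 <- cl$y
  if (identical(n_orth, "auto")) {
    q2s <- vapply(0:max_orth, function(a)
      cross_validate_q2(m, labels, folds = folds, seed = seed, n_orth = a,
                        positive = cl$positive), 0)
    n_orth <- (0:max_orth)[which.max(q2s)]
  }
  n_orth <- as.integer(n_orth)
  y <- y0 - mean(y0)
  fit <- opls_core(m, y, n_orth)
  q2 <- cross_validate_q2(m, labels, folds = folds, seed = seed,
                          n_orth = n_orth, positive = cl$positive)
  structure(
    list(
      predictive_weights = setNames(fit$w, colnames(m)),
      predictive_loadings = setNames(fit$p, colnames(m)),
      c = fit$c, orthogonal_components = fit$orth,
      n_orth = length(fit$orth), q2 = q2,
      y_mean = mean(y0), positive = cl$positive, negative = cl$negative,
      training_scores = tibble(obs_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                               label = as.character(labels),
                               score = fit$t),
      training_column_stats = attr(x, "col_stats"),
      variables = colnames(m)
    ),
    class = "oplsda_model"
  )
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "<oplsda_model> 1 predictive + %d orthogonal component(s); Q2 = %.3f; positive class: %s\n",
    x$n_orth, x$q2, x$positive))
  invisible(x)
}

#' Y-prediction scores for new observations
#'
#' Projects new observations onto the model's predictive component after
#' applying the training column scaling and removing the stored orthogonal
#' components. Positive scores indicate the positive (strong) class.
#'
#' @param model An `oplsda_model`.
#' @param newdata A `word_matrix` (raw or AT-normalized, matching the state
#'   the model was trained on; the stored training scaling is applied), an
#'   already-scaled matrix, or a plain matrix with the model's variables.
#' @param scaled Set `TRUE` if `newdata` is already scaled with the training
#'   statistics.
#' @return Tibble with `obs_id` and `score`.
#' @export
predict_scores <- function(model, newdata, scaled = FALSE) {
  stopifnot(inherits(model, "oplsda_model"))
  m <- unclass(newdata)
  if (is.null(colnames(m)) || !all(model$variables %in% colnames(m))) {
    abort("newdata lack the model's variables", class = "mslseq_schema_error")
  }
  m <- m[, model$variables, drop = FALSE]
  if (!scaled) {
    cs <- model$training_column_stats
    if (is.null(cs)) abort("model carries no column statistics; pass scaled data",
                           class = "mslseq_schema_error")
    m <- apply_col_stats(m, cs)
  }
  core <- list(w = unname(model$predictive_weights),
               orth = model$orthogonal_components)
  tibble(
    obs_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    score = opls_project(core, m)
  )
}

# stratified fold assignment, deterministic per seed
stratified_folds <- function(labels, folds, seed) {
  f <- factor(labels)
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/SS over stratified held-out folds, with Y centered on the
#' training folds; values at or below zero indicate no predictive power.
#'
#' @inheritParams fit_oplsda
#' @param x Scaled matrix or `word_matrix`.
#' @param n_orth Orthogonal components used in each fold's model (default 0).
#' @return Q2 (a number <= 1).
#' @export
cross_validate_q2 <- function(x, labels, folds = 7, seed = 1, n_orth = 0,
                              positive = NULL) {
  m <- unclass(x)
  cl <- code_labels(labels, positive)
  folds <- as.integer(folds)
  if (folds < 2L) abort("`folds` must be at least 2", class = "mslseq_parameter_error")
  if (folds > min(table(labels))) {
    abort("`folds` exceeds the smallest class size", class = "mslseq_parameter_error")
  }
  fold_of <- stratified_folds(labels, folds, seed)
  press <- 0; ss <- 0
  for (fd in seq_len(folds)) {
    tr <- fold_of != fd
    ytr <- cl$y[tr]; yte <- cl$y[!tr]
    fit <- opls_core(m[tr, , drop = FALSE], ytr - mean(ytr), n_orth)
    t_te <- opls_project(fit, m[!tr, , drop = FALSE])
    yhat <- fit$c * t_te + mean(ytr)
    press <- press + sum((yte - yhat)^2)
    ss <- ss + sum((yte - mean(ytr))^2)
  }
  1 - press / ss
}

#' Null OPLS-DA models from random gene groups
#'
#' Draws `n_groups` non-overlapping groups of `group_size` sequences, builds a
#' per-sequence word matrix for each pair of groups, and fits an OPLS-DA model
#' per pair (21 models for 7 groups). With arbitrary group membership no pair
#' should yield predictive power, so the Q2 distribution calibrates the
#' modeling pipeline's false-positive behaviour; the Spearman correlation of
#' each model's training scores with AT content flags AT-driven separations.
#'
#' @param seqs Character vector of sequences (e.g. one CDS per gene).
#' @param n_groups,group_size Number and size of the disjoint groups.
#' @param seed Seed for group sampling and CV folds.
#' @param k_min,k_max Word range for the matrices.
#' @param folds CV folds for Q2.
#' @param n_orth Orthogonal components per model (default 0).
#' @return Tibble with one row per pair: `group_a`, `group_b`, `q2`,
#'   `spearman_at`.
#' @export
random_group_null <- function(seqs, n_groups = 7, group_size = 100, seed = 1,
                              k_min = 2, k_max = 6, folds = 7, n_orth = 0) {
  n_need <- n_groups * group_size
  if (length(seqs) < n_need) {
    abort(sprintf("need %d sequences for %d groups of %d", n_need, n_groups,
                  group_size), class = "mslseq_input_error")
  }
  if (n_groups < 2L) abort("need at least two groups", class = "mslseq_input_error")
  picks <- withr::with_seed(seed, sample(length(seqs), n_need))
  group_of <- rep(seq_len(n_groups), each = group_size)
  pairs <- utils::combn(n_groups, 2L)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1L, j]; gb <- pairs[2L, j]
    idx <- picks[group_of %in% c(ga, gb)]
    labs <- ifelse(group_of[group_of %in% c(ga, gb)] == ga, "a", "b")
    sub <- seqs[idx]
    names(sub) <- sprintf("s%04d", idx)
    wm <- scale_matrix(word_matrix(sub, k_min, k_max, layout = "canonical"),
                       "uv_scaled")
    q2 <- cross_validate_q2(wm, labs, folds = folds, seed = seed + j,
                            n_orth = n_orth, positive = "a")
    fit <- fit_oplsda(wm, labs, n_orth = n_orth, positive = "a",
                      folds = folds, seed = seed + j)
    rho <- suppressWarnings(cor(fit$training_scores$score, at_content(wm),
                                method = "spearman"))
    out[[j]] <- tibble(group_a = ga, group_b = gb, q2 = q2, spearman_at = rho)
  }
  bind_rows(out)
}
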