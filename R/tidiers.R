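# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_text geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param matrix `"scores"` (default), `"loadings"` or `"r2"`.
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "r2"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "r2") {
    return(tibble(component = seq_along(x$r2cum), r2cum = x$r2cum))
  }
  m <- x[[matrix]]
  out <- tibble(
    id = rep(rownames(m), times = ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  names(out)[1L] <- if (matrix == "scores") "obs_id" else "word"
  out
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_obs = nrow(x$scores), n_components = ncol(x$scores),
         r2cum_total = x$r2cum[length(x$r2cum)])
}

#' Tidy an OPLS-DA model (sorted word loadings)
#'
#' @param x An `oplsda_model`.
#' @param ... Unused.
#' @return Tibble `word`, `weight`, `loading`, sorted by loading descending,
#'   matching the layout of a sorted word-loading export.
#' @export
tidy.oplsda_model <- function(x, ...) {
  tibble(word = names(x$predictive_loadings),
         weight = unname(x$predictive_weights),
         loading = unname(x$predictive_loadings)) |>
    arrange(desc(.data$loading))
}

#' @rdname tidy.oplsda_model
#' @export
glance.oplsda_model <- function(x, ...) {
  tibble(q2 = x$q2, n_orth = x$n_orth,
         n_obs = nrow(x$training_scores),
         positive = x$positive)
}

#' Score plot of a PCA model
#'
#' @param object A `pca_model`.
#' @param components Two components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), ...) {
  df <- tibble(
    obs_id = rownames(object$scores),
    x = object$scores[, components[1L]],
    y = object$scores[, components[2L]]
  )
  ggplot(df, aes(.data$x, .data$y)) +
    geom_point() +
    geom_text(aes(label = .data$obs_id), vjust = -0.6, size = 2.6) +
    labs(x = sprintf("PC%d", components[1L]),
         y = sprintf("PC%d", components[2L]),
         title = sprintf("PCA scores (R2cum = %.3f)",
                         object$r2cum[max(components)])) +
    theme_minimal()
}

#' Training-score distributions of an OPLS-DA model
#'
#' @param object An `oplsda_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oplsda_model <- function(object, ...) {
  ggplot(object$training_scores, aes(.data$score, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Y-prediction score", y = "genes",
         title = sprintf("OPLS-DA training scores (Q2 = %.2f)", object$q2)) +
    theme_minimal()
}

#' Sequence-logo style plot of a PWM
#'
#' Letter height is the base probability scaled by the position's information
#' content (bits).
#'
#' @param object A `pwm_motif`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm_motif <- function(object, ...) {
  df <- tidy(object) |>
    group_by(.data$position) |>
    mutate(ic = 2 + sum(ifelse(.data$prob > 0, .data$prob * log2(.data$prob), 0)),
           height = .data$prob * .data$ic) |>
    arrange(.data$height, .by_group = TRUE) |>
    mutate(top = cumsum(.data$height), mid = .data$top - .data$height / 2) |>
    ungroup()
  ggplot(df, aes(x = .data$position)) +
    geom_text(aes(y = .data$mid, label = .data$base, colour = .data$base,
                  size = .data$height), fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(0.5, 9)) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(object$columns))) +
    labs(y = "information (bits)",
         title = paste("Motif", pwm_consensus(object))) +
    theme_minimal()
}

#' Plot a binned co-localization profile
#'
#' @param profile Output of [binned_colocalization()].
#' @return A ggplot.
#' @export
plot_colocalization <- function(profile) {
  ggplot(profile, aes(.data$bin_mid, .data$mean_value)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "distance from peak center (bp; TSS to the right)",
         y = "mean log2 enrichment") +
    theme_minimal()
}

#' Plot presence fractions by MSL-enrichment bin
#'
#' @param bins Output of [binned_enrichment_summary()].
#' @return A ggplot.
#' @export
plot_enrichment_bins <- function(bins) {
  ggplot(bins, aes(.data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
                   .data$fraction)) +
    geom_col(width = (bins$bin_hi - bins$bin_lo) * 0.9) +
    labs(x = "average MSL enrichment (log2)", y = "fraction with motif") +
    theme_minimal()
}
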