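# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phylogenetic-signal result
#'
#' @param x a `phylodem_signal`.
#' @param ... unused.
#' @return one-row tibble: `statistic, estimate, sigma2, se_used, n_tips`,
#'   plus permutation/likelihood columns when present.
#' @method tidy phylodem_signal
#' @export
tidy.phylodem_signal <- function(x, ...) {
  out <- tibble::tibble(
    statistic = x$statistic_name, estimate = x$estimate, sigma2 = x$sigma2,
    se_used = isTRUE(x$se_used), n_tips = x$n_tips
  )
  if (!is.null(x$significant)) {
    out$significant <- x$significant
    out$p_value <- x$p_value
    out$band_lo <- x$perm_quantiles[1]
    out$band_hi <- x$perm_quantiles[2]
    out$perm_count <- x$perm_count
  }
  if (!is.null(x$log_likelihood)) {
    out$log_likelihood <- x$log_likelihood
    out$lambda_max <- x$lambda_max
    out$lrt_p <- x$lrt_p
  }
  out
}

#' @rdname tidy.phylodem_signal
#' @method glance phylodem_signal
#' @export
glance.phylodem_signal <- function(x, ...) tidy(x, ...)

#' Tidy a phylogenetic PCA
#'
#' @param x a `phylodem_ppca`.
#' @param matrix `"loadings"`, `"scores"` or `"eigenvalues"`.
#' @param ... unused.
#' @return long tibble of the requested component.
#' @method tidy phylodem_ppca
#' @export
tidy.phylodem_ppca <- function(x, matrix = c("loadings", "scores", "eigenvalues"),
                               ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      axis = colnames(x$loadings),
      eigenvalue = x$eigenvalues,
      proportion_variance = x$proportion_variance,
      cumulative_variance = cumsum(x$proportion_variance)
    ))
  }
  m <- x[[matrix]]
  tibble::as_tibble(m, rownames = if (matrix == "loadings") "trait" else "genus") |>
    tidyr::pivot_longer(-1, names_to = "axis", values_to = "value")
}

#' @rdname tidy.phylodem_ppca
#' @method glance phylodem_ppca
#' @export
glance.phylodem_ppca <- function(x, ...) {
  tibble::tibble(
    n_genera = x$n_genera, n_traits = length(x$traits_used),
    var_axis1 = x$proportion_variance[1],
    var_axis2 = if (length(x$proportion_variance) > 1)
      x$proportion_variance[2] else NA_real_,
    var_first_two = sum(x$proportion_variance[seq_len(min(2, length(x$proportion_variance)))])
  )
}

#' Plot the permutation null distribution against the observed statistic
#'
#' @param object a `phylodem_signal` from [permutation_test()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot phylodem_signal
#' @export
autoplot.phylodem_signal <- function(object, ...) {
  if (is.null(object$permutations)) {
    abort("autoplot needs a permutation_test() result")
  }
  df <- tibble::tibble(K = object$permutations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$perm_quantiles,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::labs(
      x = "Blomberg's K (tip-randomized)", y = "count",
      title = sprintf("Observed K = %.3f (%ssignificant at the 2.5-97.5%% band)",
                      object$estimate,
                      if (isTRUE(object$significant)) "" else "not ")
    ) +
    ggplot2::theme_minimal()
}

#' Biplot-style view of a phylogenetic PCA
#'
#' @param object a `phylodem_ppca`.
#' @param axes which two axes to show.
#' @param ... unused.
#' @return a ggplot with genus scores and trait-loading arrows.
#' @method autoplot phylodem_ppca
#' @export
autoplot.phylodem_ppca <- function(object, axes = c(1, 2), ...) {
  sc <- tibble::as_tibble(object$scores[, axes, drop = FALSE],
                          rownames = "genus")
  ld <- tibble::as_tibble(object$loadings[, axes, drop = FALSE],
                          rownames = "trait")
  ax <- colnames(object$scores)[axes]
  mult <- max(abs(sc[[ax[1]]]), abs(sc[[ax[2]]])) * 0.8
  pv <- 100 * object$proportion_variance[axes]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    ggplot2::geom_point(alpha = 0.5, size = 1.2) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1]]] * mult,
                   yend = .data[[ax[2]]] * mult),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data[[ax[1]]] * mult * 1.08,
                   y = .data[[ax[2]]] * mult * 1.08, label = .data$trait),
      colour = "firebrick", size = 3) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", ax[1], pv[1]),
                  y = sprintf("%s (%.1f%%)", ax[2], pv[2])) +
    ggplot2::theme_minimal()
}
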