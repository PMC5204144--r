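# Adjustment of genus trait values for systematic among-plot variation.
#
# Forest plots differ systematically (climate, soils, disturbance history),
# so raw genus means confound genus identity with where the genus happens to
# grow. A log-scale linear mixed model with genus fixed effects and plot
# random intercepts separates the two; genus values are reported at the
# average plot (random effect zero).

#' Genus trait values adjusted for among-plot variation
#'
#' For mean-type traits, fits `log(value) ~ 0 + genus + (1 | plot)` by
#' maximum likelihood and back-transforms the genus effects. For
#' percentile-type traits, the estimated plot intercepts are subtracted from
#' the log stem values before the genus 95th percentile is taken, so the
#' quantile itself is computed on plot-centred data.
#'
#' @param data tibble with columns `genus`, `plot_id` and `value`
#'   (stem-level, positive).
#' @param type `"mean"` or `"percentile"`.
#' @return tibble `genus, value_adj, n_stems`, with attribute
#'   `plot_sd` (among-plot standard deviation on the log scale) and
#'   `adjusted` (FALSE when the fit was degenerate and unadjusted values
#'   were returned).
#' @export
plot_adjusted_traits <- function(data, type = c("mean", "percentile")) {
  type <- match.arg(type)
  data <- dplyr::filter(data, is.finite(.data$value), .data$value > 0)
  if (nrow(data) == 0) abort("no positive stem values to adjust")

  unadjusted <- function(note) {
    warn(paste0("plot adjustment degenerate (", note, "); returning unadjusted values"))
    out <- data |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(
        value_adj = if (type == "mean") mean(.data$value) else pctl95(.data$value),
        n_stems = dplyr::n(), .groups = "drop")
    attr(out, "plot_sd") <- NA_real_
    attr(out, "adjusted") <- FALSE
    out
  }

  if (dplyr::n_distinct(data$plot_id) < 2) return(unadjusted("single plot"))

  fit <- tryCatch(
    lme4::lmer(log(value) ~ 0 + genus + (1 | plot_id), data = data,
               REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL
  )
  if (is.null(fit)) return(unadjusted("lmer failure"))

  plot_sd <- sqrt(unname(lme4::VarCorr(fit)$plot_id[1, 1]))

  if (type == "mean") {
    fe <- lme4::fixef(fit)
    genus_levels <- sub("^genus", "", names(fe))
    out <- tibble::tibble(genus = genus_levels, value_adj = exp(unname(fe))) |>
      dplyr::left_join(dplyr::count(data, .data$genus, name = "n_stems"),
                       by = "genus")
  } else {
    re <- lme4::ranef(fit)$plot_id
    offsets <- tibble::tibble(plot_id = rownames(re), offset = re[, 1])
    out <- data |>
      dplyr::left_join(offsets, by = "plot_id") |>
      dplyr::mutate(centred = exp(log(.data$value) -
                                    dplyr::coalesce(.data$offset, 0))) |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(value_adj = pctl95(.data$centred),
                       n_stems = dplyr::n(), .groups = "drop")
  }
  attr(out, "plot_sd") <- plot_sd
  attr(out, "adjusted") <- TRUE
  out
}

#' Kendall rank correlation between adjusted and unadjusted genus values
#'
#' @param adjusted,unadjusted tibbles with `genus` and a value column
#'   (`value_adj` / `value`).
#' @return Kendall's tau over genera present in both tables.
#' @export
adjustment_concordance <- function(adjusted, unadjusted) {
  joined <- dplyr::inner_join(
    adjusted[c("genus", "value_adj")], unadjusted[c("genus", "value")],
    by = "genus")
  if (nrow(joined) < 3) abort("need >= 3 genera for a rank correlation")
  cor(joined$value_adj, joined$value, method = "kendall")
}
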