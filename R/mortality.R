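# Exponential-survival mortality model.
#
# Each stem is observed over a monitoring span t (first to last census) and
# either survives or dies. Survival probability is exp(-m t) with a
# log-linear hazard ln m = alpha_g + beta * z, z the standardized log
# initial diameter and beta shared across genera. The Bernoulli likelihood
# is exactly a binomial GLM with complementary-log-log link and offset
# log(t): P(death) = 1 - exp(-exp(alpha_g + beta z + log t)).

#' Fit genus mortality rates from survival over the monitoring period
#'
#' Genera with at least `min_n` stems in demographic plots enter a joint
#' cloglog GLM (genus intercepts, shared size slope). Genera with zero
#' observed deaths sit on the likelihood boundary (hazard 0); they are
#' reported as 0 %/yr with `boundary = TRUE` and held out of the joint fit.
#' The reported rate is 100 times the mean fitted per-stem hazard.
#'
#' @param summaries stem summaries ([stem_growth_summary()]); needs
#'   `genus, init_diameter, t_monitor, survived` and (if present)
#'   `demographic_plot`.
#' @param min_n minimum stems per genus (default 100).
#' @param size_covariate include the standardized ln-initial-diameter slope
#'   (default TRUE); FALSE fits intercepts only.
#' @return tibble `genus, trait ("mortality"), value (% / yr), n_stems,
#'   n_deaths, n_species, boundary`, with attributes `beta` (size slope) and
#'   `model_note` recording that no plot random effect is included.
#' @export
fit_genus_mortality <- function(summaries, min_n = 100, size_covariate = TRUE) {
  df <- summaries
  if ("demographic_plot" %in% names(df)) {
    df <- dplyr::filter(df, .data$demographic_plot)
  }
  df <- df |>
    dplyr::filter(is.finite(.data$init_diameter), .data$init_diameter > 0,
                  is.finite(.data$t_monitor), .data$t_monitor > 0)
  counts <- dplyr::count(df, .data$genus)
  eligible <- counts$genus[counts$n >= min_n]
  df <- dplyr::filter(df, .data$genus %in% eligible)
  if (nrow(df) == 0) {
    return(tibble::tibble(genus = character(), trait = character(),
                          value = numeric(), n_stems = integer(),
                          n_deaths = integer(), n_species = integer(),
                          boundary = logical()))
  }
  df$died <- !df$survived
  df$z <- as.numeric(scale(log(df$init_diameter)))
  if (sd(log(df$init_diameter)) == 0) df$z <- 0

  deaths <- df |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(n_deaths = sum(.data$died), .groups = "drop")
  zero_death <- deaths$genus[deaths$n_deaths == 0]
  fit_df <- dplyr::filter(df, !.data$genus %in% zero_death)

  beta <- NA_real_
  beta_se <- NA_real_
  alpha <- alpha_se <- NULL
  rates <- tibble::tibble(genus = character(), value = numeric())
  if (nrow(fit_df) > 0) {
    fit_df$genus_f <- factor(fit_df$genus)
    one_genus <- nlevels(fit_df$genus_f) == 1
    with_z <- size_covariate && length(unique(fit_df$z)) > 1
    form <- if (one_genus) {
      if (with_z) died ~ 1 + z else died ~ 1
    } else {
      if (with_z) died ~ 0 + genus_f + z else died ~ 0 + genus_f
    }
    fit <- glm(form, family = stats::binomial(link = "cloglog"),
               offset = log(fit_df$t_monitor), data = fit_df)
    if (!fit$converged) {
      abort(paste0("mortality GLM did not converge; deviance = ",
                   signif(fit$deviance, 6), ", iter = ", fit$iter))
    }
    cf <- coef(fit)
    cf_se <- summary(fit)$coefficients[, "Std. Error"]
    beta <- if ("z" %in% names(cf)) unname(cf["z"]) else 0
    beta_se <- if ("z" %in% names(cf)) unname(cf_se["z"]) else NA_real_
    a_names <- if (one_genus) "(Intercept)"
               else paste0("genus_f", levels(fit_df$genus_f))
    alpha <- setNames(cf[a_names],
                      paste0("genus_f", levels(fit_df$genus_f)))
    alpha_se <- setNames(cf_se[a_names],
                         paste0("genus_f", levels(fit_df$genus_f)))
    fit_df$m_hat <- exp(alpha[paste0("genus_f", fit_df$genus)] + beta * fit_df$z)
    rates <- fit_df |>
      dplyr::group_by(genus = .data$genus) |>
      dplyr::summarise(value = 100 * mean(.data$m_hat), .groups = "drop")
  }

  out <- df |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      n_stems = dplyr::n(),
      n_deaths = sum(.data$died),
      n_species = dplyr::n_distinct(.data$species[!is.na(.data$species)]),
      .groups = "drop"
    ) |>
    dplyr::left_join(rates, by = "genus") |>
    dplyr::mutate(
      boundary = .data$genus %in% zero_death,
      value = dplyr::coalesce(.data$value, 0),
      trait = "mortality"
    ) |>
    dplyr::select("genus", "trait", "value", "n_stems", "n_deaths",
                  "n_species", "boundary")
  attr(out, "beta") <- beta
  attr(out, "beta_se") <- beta_se
  if (!is.null(alpha)) {
    nm <- sub("^genus_f", "", names(alpha))
    attr(out, "alpha") <- setNames(unname(alpha), nm)
    attr(out, "alpha_se") <- setNames(unname(alpha_se), nm)
  }
  attr(out, "model_note") <- "no plot random effect in the mortality model"
  out
}

# 1-D exponential-survival MLE without covariates; used for species-level
# mortality values feeding intrageneric standard errors
fit_exp_rate <- function(t, died) {
  if (!any(died)) return(0)
  if (all(died)) return(Inf)
  nll <- function(log_m) {
    m <- exp(log_m)
    -sum(ifelse(died, log1p(-exp(-m * t)), -m * t))
  }
  opt <- optimize(nll, c(-12, 3))
  exp(opt$minimum)
}
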