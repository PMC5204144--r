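# Assembly of the genus x trait table (the package's central deliverable):
# wood density, potential size on three scales, two size x wood-density
# products, mean and maximum growth on three scales, and mortality, each
# with an intrageneric standard error from species-level values.

size_trait_cols <- c(max_d = "max_d", max_ba = "max_ba", max_agb = "max_agb")
growth_mean_cols <- c("meangr_d", "meangr_ba", "meangr_agb")
growth_max_cols <- c("maxgr_d", "maxgr_ba", "maxgr_agb")

# species-level analogue of a genus trait (same estimator, per species)
species_trait_values <- function(df, col, fun, min_n) {
  df |>
    dplyr::filter(!is.na(.data$species), is.finite(.data[[col]])) |>
    dplyr::group_by(.data$genus, .data$species) |>
    dplyr::summarise(value = fun(.data[[col]]), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::select("genus", "species", "value")
}

attach_se <- function(trait_tbl, species_vals) {
  ses <- tryCatch(intrageneric_se(species_vals),
                  error = function(e) NULL)
  if (is.null(ses)) {
    trait_tbl$se <- NA_real_
    trait_tbl$se_imputed <- NA
    return(trait_tbl)
  }
  trait_tbl |>
    dplyr::left_join(ses[c("genus", "se", "se_imputed")], by = "genus") |>
    dplyr::mutate(
      se_imputed = dplyr::coalesce(.data$se_imputed, TRUE),
      se = dplyr::coalesce(.data$se, mean(ses$se))
    )
}

#' Build the full genus x trait table from census inputs
#'
#' Runs the stem summaries, growth exclusions, potential-size, growth,
#' wood-density and mortality estimators, attaches intrageneric standard
#' errors from species-level values, and (optionally) adds plot-adjusted
#' trait values from the log-scale mixed model.
#'
#' @param census,plots,wood_density validated, filtered inputs
#'   ([apply_selection_filters()]).
#' @param params [allometry_params()].
#' @param min_n_size,min_n_growth,min_n_mortality genus thresholds
#'   (20 / 20 / 100 stems).
#' @param min_n_species_value minimum stems for a species-level trait value
#'   feeding the intrageneric standard errors (default 5; mortality uses
#'   `4 * min_n_species_value`).
#' @param adjust_plots also compute plot-adjusted values (`value_adj`
#'   column; NA for wood density and mortality, which are not adjusted).
#' @return tibble `genus, trait, value, value_adj, se, se_imputed, n_stems,
#'   n_species`, one row per genus x available trait, with attributes
#'   `summaries` (the stem table) and `mortality_beta`.
#' @export
genus_trait_table <- function(census, plots, wood_density,
                              params = allometry_params(),
                              min_n_size = 20, min_n_growth = 20,
                              min_n_mortality = 100,
                              min_n_species_value = 5,
                              adjust_plots = FALSE) {
  summaries <- stem_growth_summary(census, plots, wood_density, params) |>
    apply_growth_exclusions()
  genera <- unique(summaries$genus)

  wd_tbl <- tryCatch(
    genus_wood_density(wood_density, genera) |>
      dplyr::mutate(n_stems = NA_integer_, se_imputed = is.na(.data$se)),
    error = function(e) NULL
  )

  size_tbls <- purrr::map(
    c("diameter", "basal_area", "biomass"),
    function(m) genus_potential_size(summaries, m, min_n = min_n_size)
  )
  size_tbl <- dplyr::bind_rows(size_tbls)

  growth_kept <- summaries |>
    dplyr::filter(!.data$growth_excluded, .data$n_intervals >= 1,
                  .data$demographic_plot)
  growth_tbl <- genus_growth_traits(summaries, min_n = min_n_growth)
  mort_tbl <- fit_genus_mortality(summaries, min_n = min_n_mortality)

  # size x wood-density products
  prod_tbl <- NULL
  if (!is.null(wd_tbl)) {
    wd_vals <- wd_tbl |> dplyr::select("genus", wd = "value", wd_se = "se")
    prod_tbl <- size_tbl |>
      dplyr::filter(.data$trait %in% c("max_d", "max_ba")) |>
      dplyr::inner_join(wd_vals, by = "genus") |>
      dplyr::mutate(trait = paste0(.data$trait, "_x_wd"),
                    value = .data$value * .data$wd) |>
      dplyr::select(-"wd", -"wd_se")
  }

  # intrageneric standard errors from species-level values
  se_for <- function(tbl, col, fun, min_n) {
    src <- if (col %in% c(growth_mean_cols, growth_max_cols)) growth_kept
           else summaries
    attach_se(tbl, species_trait_values(src, col, fun, min_n))
  }
  size_se <- purrr::map2_dfr(
    size_tbls, c("max_d", "max_ba", "max_agb"),
    function(tbl, col) se_for(tbl, col, pctl95, min_n_species_value))
  growth_se <- dplyr::bind_rows(
    purrr::map_dfr(growth_mean_cols, function(col)
      se_for(growth_tbl |> dplyr::filter(.data$trait == col), col, mean,
             min_n_species_value)),
    purrr::map_dfr(growth_max_cols, function(col)
      se_for(growth_tbl |> dplyr::filter(.data$trait == col), col, pctl95,
             min_n_species_value))
  )
  prod_se <- NULL
  if (!is.null(prod_tbl) && nrow(prod_tbl) > 0) {
    # product value scales the size value by genus wd, so its species-level
    # spread is the size spread scaled by wd
    wd_vals <- wd_tbl |> dplyr::select("genus", wd = "value")
    prod_se <- purrr::map_dfr(c("max_d", "max_ba"), function(col) {
      sp <- species_trait_values(summaries, col, pctl95, min_n_species_value) |>
        dplyr::inner_join(wd_vals, by = "genus") |>
        dplyr::mutate(value = .data$value * .data$wd) |>
        dplyr::select("genus", "species", "value")
      attach_se(prod_tbl |> dplyr::filter(.data$trait == paste0(col, "_x_wd")), sp)
    })
  }
  mort_se <- NULL
  if (nrow(mort_tbl) > 0) {
    sp_mort <- summaries |>
      dplyr::filter(.data$demographic_plot, !is.na(.data$species),
                    is.finite(.data$t_monitor), .data$t_monitor > 0) |>
      dplyr::group_by(.data$genus, .data$species) |>
      dplyr::summarise(
        value = 100 * fit_exp_rate(.data$t_monitor, !.data$survived),
        n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n >= 4 * min_n_species_value, is.finite(.data$value)) |>
      dplyr::select("genus", "species", "value")
    mort_se <- attach_se(mort_tbl |> dplyr::select(-"n_deaths", -"boundary"),
                         sp_mort)
  }

  out <- dplyr::bind_rows(wd_tbl, size_se, growth_se, prod_se, mort_se) |>
    dplyr::select("genus", "trait", "value", "se", "se_imputed",
                  "n_stems", "n_species")

  out$value_adj <- NA_real_
  if (adjust_plots) {
    adj_specs <- list(
      list(cols = names(size_trait_cols), src = summaries, type = "percentile"),
      list(cols = growth_mean_cols, src = growth_kept, type = "mean"),
      list(cols = growth_max_cols, src = growth_kept, type = "percentile")
    )
    for (spec_i in adj_specs) {
      for (col in spec_i$cols) {
        dat <- spec_i$src |>
          dplyr::select("genus", "plot_id", value = dplyr::all_of(col)) |>
          dplyr::filter(is.finite(.data$value), .data$value > 0)
        if (nrow(dat) == 0) next
        adj <- suppressWarnings(plot_adjusted_traits(dat, spec_i$type))
        idx <- out$trait == col
        m <- match(out$genus[idx], adj$genus)
        out$value_adj[idx] <- adj$value_adj[m]
      }
    }
  }

  attr(out, "summaries") <- summaries
  attr(out, "mortality_beta") <- attr(mort_tbl, "beta")
  attr(out, "mortality_note") <- attr(mort_tbl, "model_note")
  out
}
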