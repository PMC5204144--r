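# Stem-level census series -> genus-level trait estimates.
#
# The trait set mirrors the standard demographic-trait table for tropical
# forest inventories: potential size (95th percentile of per-stem maximum
# size), mean and maximum growth rate (each on diameter, basal-area and
# biomass scales), wood density, size x wood-density products, and an
# exponential-survival mortality rate.

#' Resolve the effective diameter series of each census record
#'
#' When the point of measurement (POM) is moved at a census, the record
#' carries both the reading at the original POM (`diameter`) and at the new
#' POM (`new_pom_diameter`). The effective diameter at that census is the
#' arithmetic mean of the two readings, so that growth computed across the
#' POM change is not biased by the change in measurement height. All other
#' censuses pass through unchanged. A POM-height change without a recorded
#' new-POM diameter is an error.
#'
#' @param census census tibble (rows for dead censuses are passed through
#'   with `eff_diameter = NA`).
#' @return the census tibble with an `eff_diameter` column appended.
#' @export
effective_diameter_series <- function(census) {
  out <- census |>
    dplyr::arrange(.data$stem_id, .data$date) |>
    dplyr::group_by(.data$stem_id) |>
    dplyr::mutate(
      pom_moved = .data$alive & !is.na(dplyr::lag(.data$pom_height)) &
        !is.na(.data$pom_height) &
        .data$pom_height != dplyr::lag(.data$pom_height)
    ) |>
    dplyr::ungroup()
  bad <- out$pom_moved & is.na(out$new_pom_diameter)
  if (any(bad)) {
    abort(sprintf("stem %s: POM change without new_pom_diameter",
                  out$stem_id[bad][1]))
  }
  out |>
    dplyr::mutate(
      eff_diameter = dplyr::case_when(
        !.data$alive ~ NA_real_,
        !is.na(.data$new_pom_diameter) ~
          (.data$diameter + .data$new_pom_diameter) / 2,
        TRUE ~ .data$diameter
      )
    ) |>
    dplyr::select(-"pom_moved")
}

# species-first, genus-mean-fallback wood-density lookup for a set of stems
match_wood_density <- function(stems, wood_density) {
  sp_tab <- wood_density |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::group_by(.data$genus, .data$species) |>
    dplyr::summarise(wd_sp = mean(.data$wood_density), .groups = "drop")
  gen_tab <- wood_density |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(wd_gen = mean(.data$wood_density), .groups = "drop")
  stems |>
    dplyr::left_join(sp_tab, by = c("genus", "species")) |>
    dplyr::left_join(gen_tab, by = "genus") |>
    dplyr::mutate(
      wd = dplyr::coalesce(.data$wd_sp, .data$wd_gen),
      wd_source = dplyr::case_when(
        !is.na(.data$wd_sp) ~ "species",
        !is.na(.data$wd_gen) ~ "genus",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-"wd_sp", -"wd_gen")
}

#' Summarise each stem's size and growth across its censuses
#'
#' Per census interval the annualised growth rate is the difference in
#' effective diameter (or basal area, or biomass) divided by the interval in
#' years; per stem, the mean and maximum of those interval rates, and the
#' maximum size over censuses, are retained. Biomass uses the tree or palm
#' allometry with the stem's wood density (species match first, genus mean
#' otherwise) and the plot's E, so only diameter varies within a stem.
#'
#' @param census census tibble (validated).
#' @param plots plot tibble with `E` (and `demographic` if filters were
#'   applied; otherwise all plots count as demographic).
#' @param wood_density wood-density tibble.
#' @param params [allometry_params()].
#' @return one row per stem: identity columns, `wd`, `wd_source`,
#'   growth summaries (`meangr_d`, `maxgr_d`, `meangr_ba`, `maxgr_ba`,
#'   `meangr_agb`, `maxgr_agb`, all NA for single-census stems), maximum
#'   sizes (`max_d`, `max_ba`, `max_agb`), mortality inputs (`init_diameter`,
#'   `t_monitor`, `survived`), and filter inputs (`n_intervals`,
#'   `any_gt8`, `any_non_tape`, `demographic_plot`).
#' @export
stem_growth_summary <- function(census, plots, wood_density,
                                params = allometry_params()) {
  if (nrow(census) == 0) abort("empty census")
  eff <- effective_diameter_series(census)
  if (!"demographic" %in% names(plots)) plots$demographic <- TRUE
  eff <- eff |>
    dplyr::left_join(plots[c("plot_id", "E", "demographic")], by = "plot_id")
  stems0 <- dplyr::distinct(eff, .data$stem_id, .data$genus, .data$species)
  wd_map <- match_wood_density(stems0, wood_density)[
    c("stem_id", "wd", "wd_source")]
  eff <- dplyr::left_join(eff, wd_map, by = "stem_id")

  ba <- rep(NA_real_, nrow(eff))
  agb <- rep(NA_real_, nrow(eff))
  ok_ba <- is.finite(eff$eff_diameter) & eff$eff_diameter > 0
  ba[ok_ba] <- basal_area(eff$eff_diameter[ok_ba])
  ok_agb <- ok_ba & (eff$growth_form == "palm" |
                       (is.finite(eff$wd) & eff$wd > 0)) & is.finite(eff$E)
  agb[ok_agb] <- stem_agb(eff$eff_diameter[ok_agb],
                          dplyr::coalesce(eff$wd[ok_agb], 1), eff$E[ok_agb],
                          eff$growth_form[ok_agb], params)
  eff$ba <- ba
  eff$agb <- agb

  grp <- eff |>
    dplyr::arrange(.data$stem_id, .data$date) |>
    dplyr::group_by(.data$stem_id) |>
    dplyr::mutate(
      dt = .data$date - dplyr::lag(.data$date),
      rate_d = (.data$eff_diameter - dplyr::lag(.data$eff_diameter)) / .data$dt,
      rate_ba = (.data$ba - dplyr::lag(.data$ba)) / .data$dt,
      rate_agb = (.data$agb - dplyr::lag(.data$agb)) / .data$dt
    )
  if (any(grp$dt <= 0, na.rm = TRUE)) abort("zero-length census interval")

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

  grp |>
    dplyr::summarise(
      plot_id = dplyr::first(.data$plot_id),
      genus = dplyr::first(.data$genus),
      species = dplyr::first(.data$species),
      growth_form = dplyr::first(.data$growth_form),
      wd = dplyr::first(.data$wd),
      wd_source = dplyr::first(.data$wd_source),
      demographic_plot = dplyr::first(.data$demographic),
      n_obs = dplyr::n(),
      n_intervals = sum(!is.na(.data$rate_d)),
      meangr_d = mean_or_na(.data$rate_d),
      maxgr_d = max_or_na(.data$rate_d),
      meangr_ba = mean_or_na(.data$rate_ba),
      maxgr_ba = max_or_na(.data$rate_ba),
      meangr_agb = mean_or_na(.data$rate_agb),
      maxgr_agb = max_or_na(.data$rate_agb),
      max_d = max_or_na(.data$eff_diameter),
      max_ba = max_or_na(.data$ba),
      max_agb = max_or_na(.data$agb),
      any_gt8 = any(.data$rate_d > 8, na.rm = TRUE),
      any_non_tape = any(!.data$method_tape),
      init_diameter = .data$eff_diameter[which(.data$alive)[1]],
      t_monitor = max(.data$date) - min(.data$date),
      survived = .data$alive[dplyr::n()],
      .groups = "drop"
    )
}

#' Flag stems excluded from growth-rate traits
#'
#' Exclusion reasons, applied in order: `negative` (stem mean diameter
#' growth < 0), `implausible` (any interval growing faster than 8 cm/yr,
#' taken to be a recording error), `palm` (no secondary growth), `non_tape`
#' (any diameter in the series measured without a tape). Excluded stems stay
#' in the size and wood-density traits; palms contribute to size/biomass via
#' the palm allometry.
#'
#' @param summaries tibble from [stem_growth_summary()].
#' @return the tibble with `growth_excluded` (logical) and
#'   `growth_excl_reason` (NA when kept) appended.
#' @export
apply_growth_exclusions <- function(summaries) {
  summaries |>
    dplyr::mutate(
      growth_excl_reason = dplyr::case_when(
        !is.na(.data$meangr_d) & .data$meangr_d < 0 ~ "negative",
        .data$any_gt8 ~ "implausible",
        .data$growth_form == "palm" ~ "palm",
        .data$any_non_tape ~ "non_tape",
        TRUE ~ NA_character_
      ),
      growth_excluded = !is.na(.data$growth_excl_reason)
    )
}

genus_quantile_trait <- function(df, value_col, trait_name, min_n) {
  df |>
    dplyr::filter(is.finite(.data[[value_col]])) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      trait = trait_name,
      value = pctl95(.data[[value_col]]),
      n_stems = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species[!is.na(.data$species)]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_stems >= min_n)
}

#' Genus potential size: 95th percentile of per-stem maximum size
#'
#' @param summaries stem summaries (palms included).
#' @param metric one of `"diameter"`, `"basal_area"`, `"biomass"`.
#' @param min_n minimum stems per genus (default 20).
#' @return tibble `genus, trait, value, n_stems, n_species`.
#' @export
genus_potential_size <- function(summaries, metric = c("diameter", "basal_area", "biomass"),
                                 min_n = 20) {
  metric <- match.arg(metric)
  col <- switch(metric, diameter = "max_d", basal_area = "max_ba", biomass = "max_agb")
  genus_quantile_trait(summaries, col, col, min_n)
}

#' Genus growth traits: mean growth and 95th-percentile maximum growth
#'
#' Mean-growth traits average each kept stem's mean interval rate across the
#' genus; maximum-growth traits take the 95th percentile across stems of the
#' stem-level maximum rate. Stems flagged by [apply_growth_exclusions()],
#' single-census stems, and stems in plots without two years of monitoring
#' do not contribute; the 20-stem threshold applies after those exclusions.
#'
#' @param summaries tibble from [apply_growth_exclusions()].
#' @param min_n minimum qualifying stems per genus (default 20).
#' @return tibble `genus, trait, value, n_stems, n_species` with traits
#'   `meangr_d, meangr_ba, meangr_agb, maxgr_d, maxgr_ba, maxgr_agb`.
#' @export
genus_growth_traits <- function(summaries, min_n = 20) {
  if (!"growth_excluded" %in% names(summaries)) {
    summaries <- apply_growth_exclusions(summaries)
  }
  kept <- summaries |>
    dplyr::filter(!.data$growth_excluded, .data$n_intervals >= 1,
                  .data$demographic_plot)
  mean_traits <- purrr::map_dfr(
    c("meangr_d", "meangr_ba", "meangr_agb"),
    function(col) {
      kept |>
        dplyr::filter(is.finite(.data[[col]])) |>
        dplyr::group_by(.data$genus) |>
        dplyr::summarise(
          trait = col,
          value = mean(.data[[col]]),
          n_stems = dplyr::n(),
          n_species = dplyr::n_distinct(.data$species[!is.na(.data$species)]),
          .groups = "drop"
        ) |>
        dplyr::filter(.data$n_stems >= min_n)
    }
  )
  max_traits <- purrr::map_dfr(
    c("maxgr_d", "maxgr_ba", "maxgr_agb"),
    function(col) genus_quantile_trait(kept, col, col, min_n)
  )
  dplyr::bind_rows(mean_traits, max_traits)
}

#' Intrageneric standard errors from species-level trait values
#'
#' The genus standard error is the standard error of the mean of its
#' species-level values (sd/sqrt(k), k = species with estimates, k >= 2).
#' Genera with fewer than two species-level estimates receive the mean of
#' the computable standard errors, the standard imputation when intrageneric
#' variation feeds a measurement-error-aware signal estimate.
#'
#' @param species_values tibble `genus, species, value` (one row per species).
#' @return tibble `genus, se, n_species, se_imputed`.
#' @export
intrageneric_se <- function(species_values) {
  per_genus <- species_values |>
    dplyr::filter(!is.na(.data$species), is.finite(.data$value)) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(se = se_mean(.data$value), n_species = dplyr::n(),
                     .groups = "drop")
  computable <- per_genus$se[!is.na(per_genus$se)]
  if (length(computable) == 0) {
    abort("no genus has >= 2 species-level values; cannot impute standard errors")
  }
  fill <- mean(computable)
  all_genera <- unique(species_values$genus)
  tibble::tibble(genus = all_genera) |>
    dplyr::left_join(per_genus, by = "genus") |>
    dplyr::mutate(
      n_species = dplyr::coalesce(.data$n_species, 0L),
      se_imputed = is.na(.data$se),
      se = dplyr::coalesce(.data$se, fill)
    )
}

#' Genus mean wood density
#'
#' @param wood_density wood-density tibble.
#' @param genera character vector of genera to report (others omitted).
#' @return tibble `genus, trait ("wd"), value, se, n_species` (se from
#'   [intrageneric_se()] over species-level densities).
#' @export
genus_wood_density <- function(wood_density, genera = unique(wood_density$genus)) {
  matched <- wood_density |> dplyr::filter(.data$genus %in% genera)
  if (nrow(matched) == 0) abort("no genus matched the wood-density table")
  vals <- matched |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(trait = "wd", value = mean(.data$wood_density),
                     n_species = dplyr::n_distinct(.data$species[!is.na(.data$species)]),
                     .groups = "drop")
  ses <- tryCatch(
    intrageneric_se(matched |>
                      dplyr::rename(value = "wood_density") |>
                      dplyr::select("genus", "species", "value")) |>
      dplyr::select("genus", "se"),
    error = function(e) tibble::tibble(genus = vals$genus, se = NA_real_)
  )
  dplyr::left_join(vals, ses, by = "genus")
}

#' Fold range (max/min) of a positive trait vector
#'
#' Convenience summary used when reporting how many-fold a trait varies
#' across genera.
#'
#' @param x positive numeric vector.
#' @return max(x)/min(x).
#' @export
fold_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || any(x <= 0)) abort("fold_range needs positive values")
  max(x) / min(x)
}
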