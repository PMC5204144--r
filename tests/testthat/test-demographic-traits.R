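test_that("POM changes are reconciled by averaging old and new readings", {
  cns <- dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 20),
    census_row("s1", date = 2005, diameter = 22, pom_height = 1.8,
               new_pom_diameter = 21)
  )
  eff <- effective_diameter_series(cns)
  expect_equal(eff$eff_diameter, c(20, 21.5))

  # no POM change: identity
  eff1 <- effective_diameter_series(census_row("s1", date = 2000, diameter = 20))
  expect_equal(eff1$eff_diameter, 20)

  # two successive POM changes: each census averaged independently
  cns2 <- dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 20),
    census_row("s1", date = 2004, diameter = 22, pom_height = 1.8,
               new_pom_diameter = 21),
    census_row("s1", date = 2008, diameter = 23, pom_height = 2.3,
               new_pom_diameter = 21.8)
  )
  expect_equal(effective_diameter_series(cns2)$eff_diameter,
               c(20, 21.5, 22.4))

  # POM height moved but no new-POM reading: error
  bad <- dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 20),
    census_row("s1", date = 2005, diameter = 22, pom_height = 1.8)
  )
  expect_error(effective_diameter_series(bad), "new_pom_diameter")
})

test_that("interval growth rates annualize and summarise correctly", {
  cns <- dplyr::bind_rows(
    census_row("s1", date = 0, diameter = 10),
    census_row("s1", date = 2, diameter = 12),
    census_row("s1", date = 4, diameter = 13)
  )
  s <- stem_growth_summary(cns, tiny_plots() |> dplyr::mutate(plot_id = "P1"),
                           tiny_wd())
  expect_equal(s$meangr_d, 0.75) # rates 1.0 and 0.5
  expect_equal(s$maxgr_d, 1.0)
  expect_equal(s$max_d, 13)
  expect_equal(s$n_intervals, 2)

  one <- stem_growth_summary(census_row("s1", date = 2000, diameter = 10),
                             tiny_plots(), tiny_wd())
  expect_true(is.na(one$meangr_d))
  expect_equal(one$max_d, 10)
})

test_that("growth summaries track basal-area and biomass scales", {
  cns <- dplyr::bind_rows(
    census_row("s1", date = 0, diameter = 10),
    census_row("s1", date = 2, diameter = 11)
  )
  s <- stem_growth_summary(cns, tiny_plots(), tiny_wd())
  expect_equal(s$meangr_ba, (basal_area(11) - basal_area(10)) / 2)
  wd <- 0.58 # Inga alba, species-level match
  expect_equal(s$wd, wd)
  expect_equal(s$wd_source, "species")
  expect_equal(s$meangr_agb, (tree_agb(11, wd, 0) - tree_agb(10, wd, 0)) / 2)
  expect_true(s$maxgr_ba >= s$meangr_ba)
})

test_that("growth exclusions flag the documented reasons, size is retained", {
  mk <- function(id, d2, form = "tree", tape = TRUE) dplyr::bind_rows(
    census_row(id, date = 0, diameter = 10, growth_form = form,
               method_tape = tape),
    census_row(id, date = 1, diameter = d2, growth_form = form,
               method_tape = tape)
  )
  cns <- dplyr::bind_rows(
    mk("neg", 9.9), mk("fast", 19), mk("palm1", 10.5, form = "palm"),
    mk("caliper", 10.5, tape = FALSE), mk("ok", 10.5))
  s <- apply_growth_exclusions(
    stem_growth_summary(cns, tiny_plots(), tiny_wd()))
  reasons <- setNames(s$growth_excl_reason, s$stem_id)
  expect_equal(unname(reasons[c("neg", "fast", "palm1", "caliper")]),
               c("negative", "implausible", "palm", "non_tape"))
  expect_false(s$growth_excluded[s$stem_id == "ok"])
  # palms keep their size metrics (palm allometry)
  expect_equal(s$max_d[s$stem_id == "palm1"], 10.5)
  expect_equal(s$max_agb[s$stem_id == "palm1"], palm_agb(10.5))
})

test_that("genus potential size is the interpolated 95th percentile with n >= 20", {
  sizes <- 10:29
  summaries <- tibble::tibble(
    stem_id = paste0("s", 1:20), genus = "Inga",
    species = paste0("sp", rep(1:4, 5)), max_d = sizes)
  got <- genus_potential_size(summaries, "diameter")
  expect_equal(got$value, 28.05) # h = (n-1)p + 1 interpolation oracle
  expect_equal(got$n_stems, 20L)

  # 19 stems: below threshold, omitted
  expect_equal(nrow(genus_potential_size(summaries[1:19, ], "diameter")), 0)

  # degenerate distribution
  flat <- summaries |> dplyr::mutate(max_d = 15)
  expect_equal(genus_potential_size(flat, "diameter")$value, 15)
})

test_that("genus growth traits pool stems as mean and 95th percentile", {
  base <- tibble::tibble(
    stem_id = paste0("s", 1:20), genus = "Inga",
    species = paste0("sp", rep(1:4, 5)), growth_form = "tree",
    demographic_plot = TRUE, n_intervals = 2L,
    meangr_d = 0.3, maxgr_d = seq(0.1, 2.0, by = 0.1),
    meangr_ba = NA_real_, maxgr_ba = NA_real_,
    meangr_agb = NA_real_, maxgr_agb = NA_real_,
    any_gt8 = FALSE, any_non_tape = FALSE)
  got <- genus_growth_traits(base)
  expect_equal(got$value[got$trait == "meangr_d"], 0.3)
  expect_equal(got$value[got$trait == "maxgr_d"], 1.905) # quantile oracle

  # exclusions are applied before the 20-stem threshold
  palms <- base |> dplyr::mutate(growth_form = ifelse(dplyr::row_number() <= 6,
                                                      "palm", "tree"))
  expect_equal(nrow(genus_growth_traits(palms)), 0)
})

test_that("max growth >= mean growth for every genus", {
  sim <- simulate_census(sim_config(n_genera = 12, stems_per_genus = 30,
                                    n_plots = 4, seed = 42))
  filt <- apply_selection_filters(sim$census, sim$plots)
  s <- apply_growth_exclusions(
    stem_growth_summary(filt$census, filt$plots, sim$wood_density))
  tt <- genus_growth_traits(s, min_n = 10)
  wide <- tidyr::pivot_wider(tt[c("genus", "trait", "value")],
                             names_from = "trait", values_from = "value")
  expect_true(all(wide$maxgr_d >= wide$meangr_d, na.rm = TRUE))
  expect_true(all(wide$maxgr_agb >= wide$meangr_agb, na.rm = TRUE))
})

test_that("intrageneric standard errors follow the sd/sqrt(k) + imputation rule", {
  sv <- tibble::tibble(
    genus = c("A", "A", "B", "B", "B", "C"),
    species = c("a1", "a2", "b1", "b2", "b3", "c1"),
    value = c(0.5, 0.7, 1, 2, 3, 9))
  got <- intrageneric_se(sv)
  expect_equal(got$se[got$genus == "A"], sd(c(0.5, 0.7)) / sqrt(2))
  expect_equal(got$se[got$genus == "A"], 0.1, tolerance = 1e-12)
  # C has one species: receives the mean of the computable SEs
  ses <- got$se[got$genus %in% c("A", "B")]
  expect_equal(got$se[got$genus == "C"], mean(ses))
  expect_true(got$se_imputed[got$genus == "C"])

  lone <- tibble::tibble(genus = "A", species = "a1", value = 1)
  expect_error(intrageneric_se(lone), "impute")
})

test_that("genus wood density averages species values; unmatched genera omitted", {
  got <- genus_wood_density(tiny_wd(), c("Inga", "Protium", "Cecropia"))
  expect_equal(got$value[got$genus == "Inga"], 0.6)
  expect_false("Cecropia" %in% got$genus)
  expect_error(genus_wood_density(tiny_wd(), "Cecropia"), "no genus matched")
  expect_equal(fold_range(c(0.15, 0.3, 1.2)), 8)
})
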