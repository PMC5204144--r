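test_that("simulated trees are ultrametric, labelled and reproducible", {
  tr <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(d[1], d[2])
  expect_equal(tr$tip.label, c("G0001", "G0002"))

  a <- ape::write.tree(simulate_tree(25, seed = 7))
  b <- ape::write.tree(simulate_tree(25, seed = 7))
  expect_identical(a, b)
  expect_true(ape::is.ultrametric(simulate_tree(25, seed = 7)))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("zero-rate Brownian traits collapse to the root value", {
  tr <- simulate_tree(10, seed = 2)
  X <- simulate_traits(tr, "bm", sigma2 = 0, seed = 3)
  expect_true(all(X == 0))
})

test_that("Brownian tip covariance converges to sigma2 * C", {
  tr <- simulate_tree(8, seed = 5)
  C <- phylo_vcv(tr)
  X <- simulate_traits(tr, "bm", sigma2 = 2, n_traits = 4000, seed = 6)
  emp <- tcrossprod(X) / 4000
  expect_lt(max(abs(emp - 2 * C)), 0.3)
  expect_gt(cor(emp[upper.tri(emp)], C[upper.tri(C)]), 0.98)
})

test_that("shuffled traits carry almost no phylogenetic signal on average", {
  tr <- simulate_tree(60, seed = 8)
  ks <- vapply(1:40, function(i) {
    x <- simulate_traits(tr, "shuffled", seed = 100 + i)[, 1]
    blomberg_k(x, tr)$estimate
  }, numeric(1))
  expect_lt(mean(ks), 0.5)
})

test_that("noiseless censuses reproduce the configured growth exactly", {
  cfg <- sim_config(n_genera = 6, stems_per_genus = 25, n_plots = 3,
                    stem_growth_sd = 0, plot_offset_sd = 0,
                    measurement_sd = 0, pom_change_prob = 0,
                    palm_fraction = 0, non_tape_prob = 0,
                    mortality_mean = 0, census_jitter = 0, seed = 31)
  sim <- simulate_census(cfg)
  s <- apply_growth_exclusions(
    stem_growth_summary(sim$census, sim$plots, sim$wood_density))
  got <- genus_growth_traits(s, min_n = 10) |>
    dplyr::filter(trait == "meangr_d") |>
    dplyr::left_join(sim$truth$genus_traits, by = "genus")
  expect_gt(nrow(got), 0)
  expect_equal(got$value, got$growth_mean, tolerance = 1e-12)

  # and the potential size equals the 95th percentile of true final sizes
  truth_sizes <- sim$truth$stems |>
    dplyr::mutate(final_d = d0 + growth_i * 10) |>
    dplyr::group_by(genus) |>
    dplyr::summarise(p95 = phylodem:::pctl95(final_d))
  size <- genus_potential_size(s, "diameter", min_n = 10) |>
    dplyr::left_join(truth_sizes, by = "genus")
  expect_equal(size$value, size$p95, tolerance = 1e-9)
})

test_that("every stem exercises the POM rule when pom_change_prob is 1", {
  cfg <- sim_config(n_genera = 3, stems_per_genus = 10, n_plots = 2,
                    pom_change_prob = 1, mortality_mean = 0, seed = 12)
  sim <- simulate_census(cfg)
  later <- sim$census |> dplyr::group_by(stem_id) |>
    dplyr::filter(dplyr::row_number() > 1, alive)
  expect_true(all(!is.na(later$new_pom_diameter)))
  expect_silent(effective_diameter_series(sim$census))
})

test_that("simulated mortality matches the configured hazard", {
  cfg <- sim_config(n_genera = 4, stems_per_genus = 1200, n_plots = 4,
                    mortality_mean = 0.02, mortality_beta = 0,
                    palm_fraction = 0, seed = 77)
  sim <- simulate_census(cfg, genus_traits = tibble::tibble(
    genus = sprintf("G%04d", 1:4), growth_mean = 0.25, hazard = 0.02,
    wd = 0.6))
  s <- stem_growth_summary(sim$census, sim$plots, sim$wood_density)
  got <- fit_genus_mortality(s, min_n = 100)
  expect_equal(nrow(got), 4)
  # 4800 stems over ~10 yr: the pooled estimate is within Monte-Carlo error
  expect_equal(mean(got$value), 2, tolerance = 0.1)
})

test_that("outputs are reproducible bit-for-bit from the same config", {
  cfg <- sim_config(n_genera = 5, stems_per_genus = 8, n_plots = 2, seed = 3)
  s1 <- simulate_census(cfg)
  s2 <- simulate_census(cfg)
  expect_identical(s1$census, s2$census)
  expect_identical(s1$wood_density, s2$wood_density)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("config validation rejects bad settings", {
  expect_error(sim_config(census_dates = c(2000, 1999)), "increasing")
  expect_error(sim_config(palm_fraction = 1.5), "probabilities")
  expect_error(sim_config(sigma2 = -1), ">= 0")
  expect_error(simulate_traits(simulate_tree(5, seed = 1), sigma2 = -2),
               ">= 0")
})
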