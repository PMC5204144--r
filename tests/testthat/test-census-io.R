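test_that("reading a hand-written fixture round-trips the data model", {
  paths <- write_tiny_inputs()
  inputs <- read_inputs(paths$census, paths$plots, paths$wd, paths$tree)
  expect_equal(dplyr::n_distinct(inputs$census$stem_id), 3)
  expect_equal(length(inputs$tree$tip.label), 3)
  expect_equal(nrow(inputs$plots), 1)

  # write -> re-read is bit-stable for the documented dialect
  out <- file.path(dirname(paths$census), "census_rt.csv")
  write_census(inputs$census, out)
  expect_equal(read_census(out), inputs$census)
})

test_that("ISO dates are converted to decimal years", {
  expect_equal(decimal_year("2000-01-01"), 2000)
  expect_equal(decimal_year("2000-07-02"), 2000 + 183 / 365.25)
  expect_equal(decimal_year(2004.5), 2004.5)
})

test_that("census invariant violations are rejected", {
  plots <- tiny_plots()
  zombie <- dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 10),
    census_row("s1", date = 2002, diameter = NA, alive = FALSE),
    census_row("s1", date = 2004, diameter = 11)
  )
  expect_error(validate_census(zombie, plots), "alive after a dead")

  dup <- dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 10),
    census_row("s1", date = 2000, diameter = 10)
  )
  expect_error(validate_census(dup, plots), "duplicate")

  orphan <- census_row("s1", plot_id = "NOPE", date = 2000, diameter = 10)
  expect_error(validate_census(orphan, plots), "unknown plot")
})

test_that("duplicated tip labels and absent branch lengths are rejected", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((Inga:1,Inga:1):1,Protium:2);", f)
  expect_error(read_phylogeny(f), "duplicate tip")
  writeLines("((A,B),C);", f)
  expect_error(read_phylogeny(f), "branch length")
})

test_that("selection filters exclude plots and stems with logged reasons", {
  plots <- dplyr::bind_rows(
    tiny_plots(),
    tibble::tibble(plot_id = "P2", latitude = -3, longitude = -61,
                   elevation = 100, annual_precip = 1200, E = 0, area = 1),
    tibble::tibble(plot_id = "P3", latitude = -3, longitude = -62,
                   elevation = 800, annual_precip = 2000, E = 0, area = 1),
    tibble::tibble(plot_id = "P4", latitude = -4, longitude = -60,
                   elevation = 50, annual_precip = 2500, E = 0, area = 1)
  )
  census <- dplyr::bind_rows(
    tiny_census(),
    census_row("s4", plot_id = "P2", date = 2000, diameter = 12),
    census_row("s5", plot_id = "P4", genus = "", date = 2005, diameter = 12),
    census_row("s6", plot_id = "P4", date = 2005, diameter = 12) # single census
  )
  res <- apply_selection_filters(census, plots)

  log <- res$exclusions
  expect_equal(log$reason[log$id == "P2"], "precip")
  expect_equal(log$reason[log$id == "P3"], "elevation")
  expect_true(all(log$reason[log$id == "s4"] == "plot_excluded"))
  expect_true(all(log$reason[log$id == "s5"] == "unidentified"))

  # single-census plot kept, but not usable for demographic rates
  expect_true("P4" %in% res$plots$plot_id)
  expect_false(res$plots$demographic[res$plots$plot_id == "P4"])
  expect_true(res$plots$demographic[res$plots$plot_id == "P1"])

  # partition property: kept + logged stem records = input records
  n_logged <- sum(log$unit == "stem_record")
  expect_equal(nrow(res$census) + n_logged, nrow(census))

  expect_error(
    apply_selection_filters(census, plots, min_precip = 1e5),
    "all plots excluded")
})
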