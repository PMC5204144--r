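# Fixtures built in code: a hand-sized census, plot, wood-density and tree
# set exercising every column of the documented CSV dialect.

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 5, depth = 2) {
  ape::read.tree(text = paste0(
    "(", paste0(sprintf("T%d:%g", seq_len(n), depth), collapse = ","), ");"))
}

# one row of the census table
census_row <- function(stem_id, plot_id = "P1", genus = "Inga",
                       species = "Inga alba", growth_form = "tree",
                       date, diameter, pom_height = 1.3, alive = TRUE,
                       method_tape = TRUE, new_pom_diameter = NA_real_) {
  tibble::tibble(stem_id = stem_id, plot_id = plot_id, genus = genus,
                 species = species, growth_form = growth_form, date = date,
                 diameter = diameter, pom_height = pom_height, alive = alive,
                 method_tape = method_tape,
                 new_pom_diameter = new_pom_diameter)
}

tiny_census <- function() {
  dplyr::bind_rows(
    census_row("s1", date = 2000, diameter = 10),
    census_row("s1", date = 2002, diameter = 11),
    census_row("s2", genus = "Protium", species = "Protium altum",
               date = 2000, diameter = 20),
    census_row("s2", genus = "Protium", species = "Protium altum",
               date = 2002, diameter = 20.6),
    census_row("s3", genus = "Euterpe", species = "Euterpe oleracea",
               growth_form = "palm", date = 2000, diameter = 15),
    census_row("s3", genus = "Euterpe", species = "Euterpe oleracea",
               growth_form = "palm", date = 2002, diameter = 15.2)
  )
}

tiny_plots <- function() {
  tibble::tibble(plot_id = "P1", latitude = -3, longitude = -60,
                 elevation = 100, annual_precip = 2200, E = 0, area = 1)
}

tiny_wd <- function() {
  tibble::tibble(
    genus = c("Inga", "Inga", "Protium", "Euterpe"),
    species = c("Inga alba", "Inga edulis", "Protium altum", NA),
    wood_density = c(0.58, 0.62, 0.55, 0.45)
  )
}

write_tiny_inputs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    census = file.path(dir, "census.csv"),
    plots = file.path(dir, "plots.csv"),
    wd = file.path(dir, "wd.csv"),
    tree = file.path(dir, "tree.nwk")
  )
  readr::write_csv(tiny_census(), paths$census, progress = FALSE)
  readr::write_csv(tiny_plots(), paths$plots, progress = FALSE)
  readr::write_csv(tiny_wd(), paths$wd, progress = FALSE)
  writeLines("((Inga:1,Protium:1):1,Euterpe:2);", paths$tree)
  paths
}

# independent explicit-inverse K oracle (solve(), no shared code path)
k_oracle <- function(x, C) {
  n <- length(x)
  invC <- solve(C)
  ones <- rep(1, n)
  a <- drop(t(ones) %*% invC %*% x) / drop(t(ones) %*% invC %*% ones)
  r <- x - a
  mse0 <- drop(t(r) %*% r) / (n - 1)
  mse <- drop(t(r) %*% invC %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / drop(t(ones) %*% invC %*% ones)) / (n - 1)
  (mse0 / mse) / expected
}
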