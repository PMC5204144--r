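# Synthetic phylogenies, trait evolution and multi-census stem records.
#
# The generator emulates the statistical structure the pipeline assumes:
# genus traits evolving on a pure-birth phylogeny (Brownian or
# lambda-rescaled), species-level scatter within genera, stems growing with
# genus-specific mean rates plus stem noise and log-scale plot offsets,
# exponential survival with a size effect, occasional POM changes, a palm
# fraction, measurement noise, and irregular census intervals. Truth tables
# are first-class outputs so recovery tests compare against generated truth,
# never hard-coded numbers.

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a lowland tropical forest
#' plot network: ~1-ha plots censused three times over a decade at roughly
#' five-year intervals, stems entering at the 10 cm diameter floor, mean
#' diameter growth around 0.25 cm/yr and hazards near 2 %/yr.
#'
#' @param n_genera number of genera (tree tips).
#' @param n_species_per_genus species richness per genus (recycled or
#'   sampled).
#' @param stems_per_genus stems simulated per genus.
#' @param n_plots number of plots.
#' @param plot_area plot area, ha.
#' @param census_dates baseline census dates (decimal years); each plot
#'   jitters them by up to `census_jitter` years so intervals are irregular.
#' @param census_jitter half-width of the per-plot census-date jitter, yr.
#' @param birth_rate pure-birth speciation rate for the genus phylogeny.
#' @param trait_model `"bm"`, `"lambda"` or `"shuffled"`.
#' @param sigma2 Brownian rate for trait evolution.
#' @param lambda Pagel's lambda used when `trait_model = "lambda"`.
#' @param growth_mean,growth_lsd across-genus mean diameter growth (cm/yr)
#'   and log-scale spread used to map the evolved trait onto growth rates.
#' @param stem_growth_sd stem-level growth noise, cm/yr.
#' @param plot_offset_sd among-plot offset SD on the log scale.
#' @param mortality_mean across-genus mean hazard, 1/yr.
#' @param mortality_beta shared slope of log hazard on standardized ln
#'   initial diameter.
#' @param wd_mean,wd_sd across-genus wood-density mean and SD, g/cm^3.
#' @param wd_species_sd within-genus (species) wood-density SD.
#' @param intrageneric_sd species-level scatter of the evolved trait.
#' @param measurement_sd diameter measurement noise, cm.
#' @param pom_change_prob probability a live stem's POM moves at a census.
#' @param palm_fraction fraction of stems flagged as palms.
#' @param non_tape_prob probability a stem's series was not tape-measured.
#' @param min_diameter census diameter floor, cm.
#' @param init_meanlog,init_sdlog lognormal parameters of initial diameters
#'   (truncated at `min_diameter`).
#' @param seed integer seed recorded in all outputs.
#' @return a `phylodem_simconfig` list.
#' @export
sim_config <- function(n_genera = 100,
                       n_species_per_genus = 3,
                       stems_per_genus = 120,
                       n_plots = 10,
                       plot_area = 1,
                       census_dates = c(2000, 2005, 2010),
                       census_jitter = 0.5,
                       birth_rate = 1,
                       trait_model = c("bm", "lambda", "shuffled"),
                       sigma2 = 1,
                       lambda = 0.5,
                       growth_mean = 0.25,
                       growth_lsd = 0.5,
                       stem_growth_sd = 0.15,
                       plot_offset_sd = 0.2,
                       mortality_mean = 0.02,
                       mortality_beta = -0.2,
                       wd_mean = 0.6,
                       wd_sd = 0.12,
                       wd_species_sd = 0.05,
                       intrageneric_sd = 0.2,
                       measurement_sd = 0.1,
                       pom_change_prob = 0.02,
                       palm_fraction = 0.05,
                       non_tape_prob = 0.001,
                       min_diameter = 10,
                       init_meanlog = log(15),
                       init_sdlog = 0.5,
                       seed = 1L) {
  trait_model <- match.arg(trait_model)
  cfg <- as.list(environment())
  if (is.unsorted(census_dates, strictly = TRUE)) {
    abort("census_dates must be strictly increasing")
  }
  probs <- c(pom_change_prob, palm_fraction, non_tape_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (any(c(sigma2, birth_rate, stem_growth_sd, plot_offset_sd,
            measurement_sd, mortality_mean) < 0)) {
    abort("rates and standard deviations must be >= 0")
  }
  structure(cfg, class = "phylodem_simconfig")
}

#' Simulate a pure-birth (Yule) genus phylogeny
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed (same seed, same Newick string).
#' @return ultrametric `phylo` with tips `G0001`, `G0002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2) abort("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("G%04d", seq_len(n_tips))
  tree
}

#' Simulate trait evolution on a phylogeny
#'
#' `bm`: root value 0, multivariate normal with covariance `sigma2 * C`.
#' `lambda`: same on the lambda-rescaled covariance. `shuffled`: Brownian
#' draw whose values are then randomly permuted across tips, destroying the
#' phylogenetic structure while keeping the trait distribution.
#'
#' @param tree `phylo`.
#' @param model `"bm"`, `"lambda"` or `"shuffled"`.
#' @param sigma2 Brownian rate (> 0 unless exactly zero trait variance is
#'   wanted).
#' @param lambda lambda for `model = "lambda"`.
#' @param n_traits number of independent replicate traits.
#' @param seed integer seed.
#' @return tips x n_traits matrix with tip-label rownames.
#' @export
simulate_traits <- function(tree, model = c("bm", "lambda", "shuffled"),
                            sigma2 = 1, lambda = 0.5, n_traits = 1,
                            seed = 1L) {
  model <- match.arg(model)
  if (sigma2 < 0) abort("sigma2 must be >= 0")
  set.seed(seed)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  if (model == "lambda") C <- lambda_transform(C, lambda)
  X <- if (sigma2 == 0) {
    matrix(0, n, n_traits)
  } else {
    crossprod(chol(C), matrix(rnorm(n * n_traits), n, n_traits)) * sqrt(sigma2)
  }
  if (model == "shuffled") X <- X[sample.int(n), , drop = FALSE]
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("trait_", seq_len(n_traits))
  X
}

#' Species-level draws around genus trait values
#'
#' @param genus_values named numeric vector of genus values.
#' @param n_species species per genus (recycled).
#' @param sd intrageneric standard deviation.
#' @param seed integer seed.
#' @return tibble `genus, species, value`.
#' @export
simulate_species_values <- function(genus_values, n_species = 3, sd = 0.2,
                                    seed = 1L) {
  set.seed(seed)
  k <- rep_len(n_species, length(genus_values))
  purrr::map2_dfr(names(genus_values), seq_along(genus_values), function(g, i) {
    tibble::tibble(
      genus = g,
      species = paste0(g, "_sp", seq_len(k[i])),
      value = rnorm(k[i], genus_values[i], sd)
    )
  })
}

# map an evolved (unit-scale) trait onto a positive rate via a lognormal link
positive_link <- function(z, mean_target, lsd) {
  z_std <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  unname(mean_target * exp(lsd * z_std - lsd^2 / 2))
}

#' Simulate a multi-census stem dataset with known truth
#'
#' Evolves genus-level growth, mortality and wood-density traits on a
#' simulated phylogeny (or uses supplied values), then generates stems,
#' censuses them at irregular plot-specific dates, applies growth, survival,
#' measurement noise, POM changes and a palm fraction, and returns the four
#' pipeline inputs plus a truth table of every generating parameter.
#'
#' @param config a [sim_config()].
#' @param genus_traits optional tibble `genus, growth_mean, hazard, wd`
#'   overriding the evolved trait values (rows must cover
#'   `config$n_genera` genera).
#' @return list: `census`, `plots`, `wood_density` (pipeline-ready tibbles),
#'   `tree` (`phylo`), `truth` (list: `config`, `genus_traits`, `stems`,
#'   `plot_offsets`, `seed`).
#' @export
simulate_census <- function(config = sim_config(), genus_traits = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_genera, birth = cfg$birth_rate, death = 0)
  tree$tip.label <- sprintf("G%04d", seq_len(cfg$n_genera))

  if (is.null(genus_traits)) {
    Z <- simulate_traits(tree, model = cfg$trait_model, sigma2 = cfg$sigma2,
                         lambda = cfg$lambda, n_traits = 3,
                         seed = cfg$seed + 1L)
    genus_traits <- tibble::tibble(
      genus = rownames(Z),
      growth_mean = positive_link(Z[, 1], cfg$growth_mean, cfg$growth_lsd),
      hazard = positive_link(Z[, 2], cfg$mortality_mean, 0.5),
      wd = unname(pmax(cfg$wd_mean + cfg$wd_sd *
                         (if (sd(Z[, 3]) > 0) (Z[, 3] - mean(Z[, 3])) / sd(Z[, 3])
                          else Z[, 3] * 0),
                       0.1))
    )
  }
  stopifnot(all(c("genus", "growth_mean", "hazard", "wd") %in% names(genus_traits)))

  set.seed(cfg$seed + 2L)
  genera <- genus_traits$genus
  plots <- tibble::tibble(
    plot_id = sprintf("P%03d", seq_len(cfg$n_plots)),
    latitude = runif(cfg$n_plots, -10, 0),
    longitude = runif(cfg$n_plots, -70, -55),
    elevation = runif(cfg$n_plots, 0, 400),
    annual_precip = runif(cfg$n_plots, 1500, 3000),
    E = runif(cfg$n_plots, -0.1, 0.2),
    area = cfg$plot_area
  )
  plot_offsets <- setNames(
    if (cfg$plot_offset_sd > 0) rnorm(cfg$n_plots, 0, cfg$plot_offset_sd)
    else rep(0, cfg$n_plots),
    plots$plot_id)
  plot_dates <- lapply(seq_len(cfg$n_plots), function(i) {
    cfg$census_dates +
      if (cfg$census_jitter > 0) runif(length(cfg$census_dates),
                                       -cfg$census_jitter, cfg$census_jitter)
      else 0
  })
  names(plot_dates) <- plots$plot_id

  n_stems <- cfg$n_genera * cfg$stems_per_genus
  stems <- tibble::tibble(
    stem_id = sprintf("S%06d", seq_len(n_stems)),
    genus = rep(genera, each = cfg$stems_per_genus),
    plot_id = sample(plots$plot_id, n_stems, replace = TRUE),
    growth_form = ifelse(runif(n_stems) < cfg$palm_fraction, "palm", "tree"),
    non_tape = runif(n_stems) < cfg$non_tape_prob
  )
  k_sp <- rep_len(cfg$n_species_per_genus, cfg$n_genera)
  names(k_sp) <- genera
  stems$species <- paste0(stems$genus, "_sp",
                          vapply(stems$genus, function(g)
                            sample.int(k_sp[[g]], 1), integer(1)))

  stems <- dplyr::left_join(stems, genus_traits, by = "genus")
  stems$d0 <- truncated_lognormal(n_stems, cfg$init_meanlog, cfg$init_sdlog,
                                  cfg$min_diameter)
  z <- log(stems$d0)
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  stems$hazard_i <- stems$hazard * exp(cfg$mortality_beta * z)
  stems$growth_i <- stems$growth_mean * exp(plot_offsets[stems$plot_id]) +
    if (cfg$stem_growth_sd > 0) rnorm(n_stems, 0, cfg$stem_growth_sd) else 0

  # walk each stem through its plot's census dates
  stems$died <- FALSE
  stems$died_at <- NA_real_
  rows <- vector("list", n_stems)
  for (i in seq_len(n_stems)) {
    dates <- plot_dates[[stems$plot_id[i]]]
    nc <- length(dates)
    true_d <- stems$d0[i] + stems$growth_i[i] * (dates - dates[1])
    alive <- TRUE
    pom <- 1.3
    rec <- vector("list", nc)
    died_at <- NA_real_
    for (j in seq_len(nc)) {
      if (!alive) break
      if (j > 1) {
        dt <- dates[j] - dates[j - 1]
        if (runif(1) > exp(-stems$hazard_i[i] * dt)) {
          # death documented at this census, then the stem leaves the record
          rec[[j]] <- list(date = dates[j], diameter = NA_real_,
                           pom_height = pom, alive = FALSE,
                           new_pom_diameter = NA_real_)
          alive <- FALSE
          died_at <- dates[j]
          break
        }
      }
      obs_d <- true_d[j] +
        if (cfg$measurement_sd > 0) rnorm(1, 0, cfg$measurement_sd) else 0
      obs_d <- max(obs_d, 0.1)
      new_pom_d <- NA_real_
      if (j > 1 && runif(1) < cfg$pom_change_prob) {
        pom <- pom + 0.5
        new_pom_d <- max(obs_d - 1, 0.1) # reading at the raised POM
      }
      rec[[j]] <- list(date = dates[j], diameter = obs_d, pom_height = pom,
                       alive = TRUE, new_pom_diameter = new_pom_d)
    }
    rec <- dplyr::bind_rows(rec[!vapply(rec, is.null, logical(1))])
    rec$stem_id <- stems$stem_id[i]
    rows[[i]] <- rec
    stems$died[i] <- !alive
    stems$died_at[i] <- died_at
  }
  census <- dplyr::bind_rows(rows) |>
    dplyr::left_join(stems[c("stem_id", "plot_id", "genus", "species",
                             "growth_form", "non_tape")],
                     by = "stem_id") |>
    dplyr::mutate(method_tape = !.data$non_tape) |>
    dplyr::select("stem_id", "plot_id", "genus", "species", "growth_form",
                  "date", "diameter", "pom_height", "alive", "method_tape",
                  "new_pom_diameter") |>
    dplyr::arrange(.data$stem_id, .data$date)

  set.seed(cfg$seed + 3L)
  wood_density <- purrr::map_dfr(seq_along(genera), function(i) {
    tibble::tibble(
      genus = genera[i],
      species = paste0(genera[i], "_sp", seq_len(k_sp[i])),
      wood_density = pmax(genus_traits$wd[i] +
                            rnorm(k_sp[i], 0, cfg$wd_species_sd), 0.05)
    )
  })

  list(
    census = census,
    plots = plots,
    wood_density = wood_density,
    tree = tree,
    truth = list(config = cfg, genus_traits = genus_traits,
                 stems = stems, plot_offsets = plot_offsets,
                 seed = cfg$seed)
  )
}

truncated_lognormal <- function(n, meanlog, sdlog, floor) {
  out <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- out < floor)) {
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  out
}

#' Write a simulated dataset to the pipeline's CSV/Newick dialects
#'
#' @param sim output of [simulate_census()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    census = file.path(dir, "census.csv"),
    plots = file.path(dir, "plots.csv"),
    wood_density = file.path(dir, "wood_density.csv"),
    tree = file.path(dir, "phylogeny.nwk"),
    config = file.path(dir, "sim_config.yaml")
  )
  readr::write_csv(sim$census, paths["census"], progress = FALSE)
  readr::write_csv(sim$plots, paths["plots"], progress = FALSE)
  readr::write_csv(sim$wood_density, paths["wood_density"], progress = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  yaml::write_yaml(unclass(sim$truth$config), paths["config"])
  paths
}
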