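# End-to-end orchestration: simulate -> traits -> signal -> ppca, with the
# sensitivity modes (spatial subset, species-level taxa, complete-trait
# genera), a manifest per run, and CSV outputs mirroring the standard
# trait/signal summary tables.

#' Run configuration for the pipeline
#'
#' @param census_path,plot_path,wd_path,newick_path input files ("traits"
#'   and later stages); filled in automatically after a "simulate" stage.
#' @param out_dir output directory.
#' @param min_precip,max_elev,min_monitoring plot selection filters
#'   (mm/yr, m, yr).
#' @param min_n_size,min_n_growth,min_n_mortality genus stem thresholds.
#' @param n_perm tip randomizations for significance (default 1000).
#' @param use_se compute the error-aware signal variants as well.
#' @param taxon_level `"genus"` or `"species"` (species-level sensitivity
#'   mode: species become the analysis taxa and the phylogeny must have
#'   species tips).
#' @param spatial_subset optional `list(lat = , lon = , radius_km = )`:
#'   restrict to plots within a great-circle radius of a centre, the
#'   "single landscape" sensitivity mode.
#' @param complete_traits_only restrict signal estimation to taxa that have
#'   every trait.
#' @param adjust_plots also analyse plot-adjusted trait values.
#' @param signal_traits traits carried into the signal and PPCA stages;
#'   default is the full trait table.
#' @param ppca_traits traits entering the PPCA (default: wood density,
#'   potential diameter, maximum diameter growth, mortality).
#' @param sim [sim_config()] used by the "simulate" stage.
#' @param seed integer master seed.
#' @return a `phylodem_runconfig` list.
#' @export
run_config <- function(census_path = NULL, plot_path = NULL, wd_path = NULL,
                       newick_path = NULL, out_dir = tempfile("phylodem_run_"),
                       min_precip = 1300, max_elev = 500, min_monitoring = 2,
                       min_n_size = 20, min_n_growth = 20,
                       min_n_mortality = 100, n_perm = 1000, use_se = TRUE,
                       taxon_level = c("genus", "species"),
                       spatial_subset = NULL, complete_traits_only = FALSE,
                       adjust_plots = FALSE,
                       signal_traits = NULL,
                       ppca_traits = c("wd", "max_d", "maxgr_d", "mortality"),
                       sim = sim_config(), seed = 1L) {
  taxon_level <- match.arg(taxon_level)
  if (!is.null(spatial_subset)) {
    stopifnot(all(c("lat", "lon", "radius_km") %in% names(spatial_subset)))
    if (spatial_subset$radius_km <= 0) abort("radius_km must be > 0")
  }
  if (min_n_size < 1 || min_n_growth < 1 || min_n_mortality < 1) {
    abort("thresholds must be >= 1")
  }
  structure(as.list(environment()), class = "phylodem_runconfig")
}

subset_plots_spatially <- function(plots, subset) {
  d_km <- geosphere::distHaversine(
    cbind(plots$longitude, plots$latitude),
    c(subset$lon, subset$lat)) / 1000
  plots[d_km <= subset$radius_km, , drop = FALSE]
}

# species-level sensitivity mode: species become the analysis taxa
promote_species <- function(census, wood_density) {
  census <- census |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::mutate(genus = .data$species, species = NA_character_)
  wood_density <- wood_density |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::mutate(genus = .data$species, species = NA_character_)
  list(census = census, wood_density = wood_density)
}

#' Phylogenetic-signal table for every trait
#'
#' For each trait in the table, computes Blomberg's K with tip-randomization
#' significance (with and, if requested, without the intrageneric standard
#' errors) and Pagel's lambda with its likelihood-ratio test.
#'
#' @param trait_table output of [genus_trait_table()] (columns `genus`,
#'   `trait`, `value`, `se`; `value_adj` used when `adjusted = TRUE`).
#' @param tree phylogeny whose tips are the analysis taxa.
#' @param n_perm,seed randomization settings.
#' @param use_se also compute the error-aware K (needs an `se` column).
#' @param adjusted analyse `value_adj` instead of `value`.
#' @param min_tips smallest number of taxa with data for a trait to be
#'   analysed (default 4).
#' @return tibble: `trait, statistic, se_used, estimate, sigma2,
#'   significant, p_value, band_lo, band_hi, lambda_loglik, lrt_p, n_tips,
#'   seed`.
#' @export
phylo_signal_table <- function(trait_table, tree, n_perm = 1000, seed = 1L,
                               use_se = TRUE, adjusted = FALSE,
                               min_tips = 4) {
  value_col <- if (adjusted) "value_adj" else "value"
  traits <- unique(trait_table$trait)
  res <- list()
  for (i in seq_along(traits)) {
    tt <- trait_table |>
      dplyr::filter(.data$trait == traits[i],
                    is.finite(.data[[value_col]]),
                    .data$genus %in% tree$tip.label)
    if (nrow(tt) < min_tips || sd(tt[[value_col]]) == 0) next
    sub <- ape::keep.tip(tree, tt$genus)
    x <- setNames(tt[[value_col]], tt$genus)
    se <- if ("se" %in% names(tt)) setNames(tt$se, tt$genus) else NULL
    variants <- list(list(use = FALSE, se = NULL))
    if (use_se && !is.null(se) && all(is.finite(se))) {
      variants <- c(variants, list(list(use = TRUE, se = se)))
    }
    for (v in variants) {
      k <- suppressWarnings(
        permutation_test(x, sub, se = v$se, n_perm = n_perm,
                         seed = seed + i))
      res[[length(res) + 1]] <- tibble::tibble(
        trait = traits[i], statistic = "K", se_used = v$use,
        estimate = k$estimate, sigma2 = k$sigma2,
        significant = k$significant, p_value = k$p_value,
        band_lo = k$perm_quantiles[1], band_hi = k$perm_quantiles[2],
        lambda_loglik = NA_real_, lrt_p = NA_real_,
        n_tips = k$n_tips, seed = k$seed
      )
      lam <- suppressWarnings(pagel_lambda(x, sub, se = v$se))
      res[[length(res) + 1]] <- tibble::tibble(
        trait = traits[i], statistic = "lambda", se_used = v$use,
        estimate = lam$estimate, sigma2 = lam$sigma2,
        significant = lam$lrt_p < 0.05, p_value = lam$lrt_p,
        band_lo = NA_real_, band_hi = NA_real_,
        lambda_loglik = lam$log_likelihood, lrt_p = lam$lrt_p,
        n_tips = lam$n_tips, seed = seed + i
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Phylogenetic PCA from a trait table
#'
#' Builds the taxa x trait matrix for the requested traits, keeps
#' complete-trait taxa, standardizes columns, and runs [ppca()] on the
#' matching subtree.
#'
#' @inheritParams phylo_signal_table
#' @param traits trait names forming the matrix.
#' @return a `phylodem_ppca`.
#' @export
ppca_from_traits <- function(trait_table, tree,
                             traits = c("wd", "max_d", "maxgr_d", "mortality"),
                             adjusted = FALSE) {
  value_col <- if (adjusted) "value_adj" else "value"
  wide <- trait_table |>
    dplyr::filter(.data$trait %in% traits) |>
    dplyr::select("genus", "trait", value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  wide <- wide[wide$genus %in% tree$tip.label, , drop = FALSE]
  missing <- setdiff(traits, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("trait(s) absent from table: %s",
                  paste(missing, collapse = ", ")))
  }
  X <- as.matrix(wide[traits])
  rownames(X) <- wide$genus
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(traits)) abort("too few complete-trait taxa for a PPCA")
  sub <- ape::keep.tip(tree, rownames(X))
  ppca(standardize_traits(X), tree = sub)
}

write_manifest <- function(path, stage, cfg, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("phylodem")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run the pipeline end to end or stage by stage
#'
#' Stages: `"simulate"` (generate inputs with the synthetic-data module),
#' `"traits"` (filter and derive the genus trait table), `"signal"`
#' (Blomberg's K and Pagel's lambda per trait), `"ppca"`, or `"all"`
#' (traits + signal + ppca; preceded by simulate when no input paths are
#' configured). Each stage writes its CSV artifacts and a JSON manifest
#' recording the seed, a config hash and the filter counts, into
#' `config$out_dir`.
#'
#' @param stages character vector of stages, in order.
#' @param config a [run_config()].
#' @return list of in-memory stage results (`inputs`, `trait_table`,
#'   `signal`, `ppca`, `manifest_paths`), invisibly.
#' @export
run_pipeline <- function(stages = "all", config = run_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (identical(stages, "all")) {
    stages <- c("traits", "signal", "ppca")
    if (is.null(cfg$census_path)) stages <- c("simulate", stages)
  }
  state <- list(manifest_paths = character())

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- simulate_census(cfg$sim)
      paths <- write_simulated_inputs(sim, file.path(cfg$out_dir, "inputs"))
      cfg$census_path <- paths[["census"]]
      cfg$plot_path <- paths[["plots"]]
      cfg$wd_path <- paths[["wood_density"]]
      cfg$newick_path <- paths[["tree"]]
      state$sim <- sim
      mp <- file.path(cfg$out_dir, "manifest_simulate.json")
      write_manifest(mp, "simulate", cfg,
                     list(n_stems = dplyr::n_distinct(sim$census$stem_id),
                          n_plots = nrow(sim$plots),
                          n_genera = length(sim$tree$tip.label)))
      state$manifest_paths <- c(state$manifest_paths, mp)
    } else if (stage == "traits") {
      if (is.null(cfg$census_path)) {
        abort("traits stage requires inputs; run the simulate stage or set input paths")
      }
      inputs <- read_inputs(cfg$census_path, cfg$plot_path, cfg$wd_path,
                            cfg$newick_path)
      if (!is.null(cfg$spatial_subset)) {
        inputs$plots <- subset_plots_spatially(inputs$plots, cfg$spatial_subset)
        if (nrow(inputs$plots) == 0) abort("spatial subset removed every plot")
        inputs$census <- inputs$census |>
          dplyr::filter(.data$plot_id %in% inputs$plots$plot_id)
      }
      if (cfg$taxon_level == "species") {
        sp <- promote_species(inputs$census, inputs$wood_density)
        inputs$census <- sp$census
        inputs$wood_density <- sp$wood_density
      }
      filtered <- apply_selection_filters(
        inputs$census, inputs$plots, min_precip = cfg$min_precip,
        max_elev = cfg$max_elev, min_monitoring = cfg$min_monitoring)
      trait_table <- genus_trait_table(
        filtered$census, filtered$plots, inputs$wood_density,
        min_n_size = cfg$min_n_size, min_n_growth = cfg$min_n_growth,
        min_n_mortality = cfg$min_n_mortality,
        adjust_plots = cfg$adjust_plots)
      readr::write_csv(trait_table, file.path(cfg$out_dir, "trait_table.csv"),
                       progress = FALSE)
      readr::write_csv(filtered$exclusions,
                       file.path(cfg$out_dir, "exclusion_log.csv"),
                       progress = FALSE)
      state$inputs <- inputs
      state$filtered <- filtered
      state$trait_table <- trait_table
      mp <- file.path(cfg$out_dir, "manifest_traits.json")
      write_manifest(mp, "traits", cfg, list(
        n_plots_kept = nrow(filtered$plots),
        n_plots_demographic = sum(filtered$plots$demographic),
        n_stem_records_kept = nrow(filtered$census),
        n_exclusions = nrow(filtered$exclusions),
        n_taxa = dplyr::n_distinct(trait_table$genus),
        mortality_note = attr(trait_table, "mortality_note") %||% NA))
      state$manifest_paths <- c(state$manifest_paths, mp)
    } else if (stage == "signal") {
      if (is.null(state$trait_table)) {
        tt_path <- file.path(cfg$out_dir, "trait_table.csv")
        if (!file.exists(tt_path)) {
          abort("signal stage requires the traits stage to have run")
        }
        state$trait_table <- readr::read_csv(tt_path, show_col_types = FALSE)
        state$inputs <- list(tree = read_phylogeny(cfg$newick_path))
      }
      tt <- state$trait_table
      if (cfg$complete_traits_only) {
        complete <- tt |>
          dplyr::group_by(.data$genus) |>
          dplyr::filter(dplyr::n() == dplyr::n_distinct(tt$trait)) |>
          dplyr::pull(.data$genus) |> unique()
        tt <- dplyr::filter(tt, .data$genus %in% complete)
      }
      traits_wanted <- cfg$signal_traits %||% unique(tt$trait)
      tt <- dplyr::filter(tt, .data$trait %in% traits_wanted)
      signal <- phylo_signal_table(tt, state$inputs$tree, n_perm = cfg$n_perm,
                                   seed = cfg$seed, use_se = cfg$use_se)
      if (cfg$adjust_plots && any(is.finite(tt$value_adj))) {
        adj <- phylo_signal_table(tt, state$inputs$tree, n_perm = cfg$n_perm,
                                  seed = cfg$seed, use_se = cfg$use_se,
                                  adjusted = TRUE)
        signal <- dplyr::bind_rows(
          dplyr::mutate(signal, adjusted = FALSE),
          dplyr::mutate(adj, adjusted = TRUE))
      } else {
        signal$adjusted <- FALSE
      }
      readr::write_csv(signal, file.path(cfg$out_dir, "signal_results.csv"),
                       progress = FALSE)
      state$signal <- signal
      mp <- file.path(cfg$out_dir, "manifest_signal.json")
      write_manifest(mp, "signal", cfg,
                     list(n_perm = cfg$n_perm, n_traits = length(unique(signal$trait))))
      state$manifest_paths <- c(state$manifest_paths, mp)
    } else if (stage == "ppca") {
      if (is.null(state$trait_table)) {
        abort("ppca stage requires the traits stage to have run")
      }
      fit <- ppca_from_traits(state$trait_table, state$inputs$tree,
                              traits = cfg$ppca_traits)
      readr::write_csv(
        tibble::as_tibble(fit$loadings, rownames = "trait"),
        file.path(cfg$out_dir, "ppca_loadings.csv"), progress = FALSE)
      readr::write_csv(
        tibble::as_tibble(fit$scores, rownames = "genus"),
        file.path(cfg$out_dir, "ppca_scores.csv"), progress = FALSE)
      readr::write_csv(
        tibble::tibble(axis = paste0("PPCA", seq_along(fit$eigenvalues)),
                       eigenvalue = fit$eigenvalues,
                       percent_variance = 100 * fit$proportion_variance),
        file.path(cfg$out_dir, "ppca_axes.csv"), progress = FALSE)
      state$ppca <- fit
      mp <- file.path(cfg$out_dir, "manifest_ppca.json")
      write_manifest(mp, "ppca", cfg,
                     list(n_genera = fit$n_genera,
                          traits = paste(fit$traits_used, collapse = ",")))
      state$manifest_paths <- c(state$manifest_paths, mp)
    } else {
      abort(sprintf("unknown stage: %s", stage))
    }
  }
  invisible(state)
}
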