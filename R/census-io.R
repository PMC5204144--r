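# Reading, validation and selection filtering of the four pipeline inputs:
# stem-level census table, plot metadata, wood-density table and the genus
# phylogeny. All tables are plain UTF-8 CSV with a mandatory header row.

census_cols <- c(
  "stem_id", "plot_id", "genus", "species", "growth_form",
  "date", "diameter", "pom_height", "alive", "method_tape",
  "new_pom_diameter"
)

plot_cols <- c(
  "plot_id", "latitude", "longitude", "elevation", "annual_precip",
  "E", "area"
)

wd_cols <- c("genus", "species", "wood_density")

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a stem-level census table
#'
#' One row per stem per census. Dates may be ISO-8601 strings or decimal
#' years; they are stored internally as decimal years. `new_pom_diameter` is
#' non-missing only at a census where the point of measurement (POM) was
#' moved: `diameter` is then the reading at the original POM and
#' `new_pom_diameter` the reading at the new POM.
#'
#' @param path CSV with columns `stem_id, plot_id, genus, species,
#'   growth_form, date, diameter, pom_height, alive, method_tape,
#'   new_pom_diameter`.
#' @return tibble ordered by stem and date.
#' @export
read_census <- function(path) {
  df <- read_checked_csv(path, census_cols, "census")
  df <- dplyr::mutate(
    df,
    stem_id = as.character(.data$stem_id),
    plot_id = as.character(.data$plot_id),
    genus = as.character(.data$genus),
    species = as.character(.data$species),
    growth_form = as.character(.data$growth_form),
    date = decimal_year(.data$date),
    alive = as.logical(.data$alive),
    method_tape = as.logical(.data$method_tape)
  )
  bad_form <- !df$growth_form %in% c("tree", "palm")
  if (any(bad_form)) {
    abort(sprintf("census row %d: growth_form must be 'tree' or 'palm'",
                  which(bad_form)[1]))
  }
  dplyr::arrange(df, .data$stem_id, .data$date)
}

#' Read the plot metadata table
#'
#' @param path CSV with columns `plot_id, latitude, longitude, elevation,
#'   annual_precip, E, area` (elevation m, precipitation mm/yr, area ha, E
#'   dimensionless environmental stress).
#' @return tibble, one row per plot.
#' @export
read_plots <- function(path) {
  df <- read_checked_csv(path, plot_cols, "plot")
  df <- dplyr::mutate(df, plot_id = as.character(.data$plot_id))
  if (anyDuplicated(df$plot_id)) abort("duplicate plot_id in plot table")
  if (any(!is.finite(df$area) | df$area <= 0)) abort("plot area must be > 0")
  if (any(!is.finite(df$E))) abort("plot E must be finite")
  df
}

#' Read the wood-density table
#'
#' Emulates a species-level wood-density compilation: one row per taxon with
#' density in g cm^-3. `species` may be missing for genus-level entries.
#'
#' @param path CSV with columns `genus, species, wood_density`.
#' @return tibble.
#' @export
read_wood_density <- function(path) {
  df <- read_checked_csv(path, wd_cols, "wood-density")
  df <- dplyr::mutate(df, genus = as.character(.data$genus),
                      species = as.character(.data$species))
  if (any(!is.finite(df$wood_density) | df$wood_density <= 0)) {
    abort("wood_density must be positive")
  }
  df
}

#' Read a rooted phylogeny with branch lengths
#'
#' @param path Newick file; tips are genera (or species in species-level
#'   sensitivity runs).
#' @return an `ape` `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) abort(sprintf("phylogeny file not found: %s", path))
  tree <- ape::read.tree(path)
  check_tree(tree)
  tree
}

check_tree <- function(tree) {
  if (is.null(tree) || !inherits(tree, "phylo")) abort("could not parse Newick tree")
  if (is.null(tree$edge.length)) abort("phylogeny has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0)) {
    abort("phylogeny has zero-length, negative or missing branch lengths")
  }
  # a single-internal-node star is accepted as rooted; a basal trifurcation
  # on a larger tree is taken to mean the tree is unrooted
  if (!ape::is.rooted(tree) && tree$Nnode > 1) abort("phylogeny must be rooted")
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf("duplicate tip label in phylogeny: %s",
                  tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  invisible(tree)
}

#' Validate census invariants against the plot table
#'
#' Checks that stems reference known plots, that no (stem, date) pair is
#' duplicated, that dates increase within a stem, that live stems have
#' positive diameters, and that no stem is recorded alive after a death.
#'
#' @param census tibble from [read_census()].
#' @param plots tibble from [read_plots()].
#' @return the census tibble, invisibly, if valid; otherwise an error.
#' @export
validate_census <- function(census, plots) {
  unknown <- setdiff(unique(census$plot_id), plots$plot_id)
  if (length(unknown) > 0) {
    abort(sprintf("stem(s) reference unknown plot: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(census[c("stem_id", "date")])) {
    abort("duplicate (stem_id, date) record in census")
  }
  by_stem <- split(seq_len(nrow(census)), census$stem_id)
  for (idx in by_stem) {
    d <- census$date[idx]
    if (is.unsorted(d, strictly = TRUE)) {
      abort(sprintf("stem %s: census dates not strictly increasing",
                    census$stem_id[idx[1]]))
    }
    a <- census$alive[idx]
    if (any(a & cumsum(!a) > 0)) {
      abort(sprintf("stem %s: recorded alive after a dead record",
                    census$stem_id[idx[1]]))
    }
    if (any(a & (!is.finite(census$diameter[idx]) | census$diameter[idx] <= 0))) {
      abort(sprintf("stem %s: live record with non-positive diameter",
                    census$stem_id[idx[1]]))
    }
  }
  invisible(census)
}

#' Read and validate all four pipeline inputs
#'
#' @param census_path,plot_path,wd_path,newick_path file paths.
#' @return list with elements `census`, `plots`, `wood_density`, `tree`.
#' @export
read_inputs <- function(census_path, plot_path, wd_path, newick_path) {
  census <- read_census(census_path)
  plots <- read_plots(plot_path)
  wd <- read_wood_density(wd_path)
  tree <- read_phylogeny(newick_path)
  validate_census(census, plots)
  list(census = census, plots = plots, wood_density = wd, tree = tree)
}

#' Apply the plot- and stem-selection filters
#'
#' Drops plots outside the precipitation/elevation envelope of lowland moist
#' forest, flags which plots have enough repeated monitoring for demographic
#' rates, and drops stems not identified to genus. Every exclusion is logged
#' with a reason code so that the kept set plus the log reconstruct the
#' input exactly.
#'
#' @param census,plots validated tibbles.
#' @param min_precip minimum annual precipitation, mm/yr (default 1300).
#' @param max_elev maximum elevation, m (default 500).
#' @param min_monitoring minimum total monitoring span, years, for a plot to
#'   contribute to growth/mortality traits (default 2).
#' @return list: `census` (kept stems), `plots` (kept plots, with a logical
#'   `demographic` column marking plots usable for growth/mortality),
#'   `exclusions` (tibble of `unit`, `id`, `reason`).
#' @export
apply_selection_filters <- function(census, plots,
                                    min_precip = 1300,
                                    max_elev = 500,
                                    min_monitoring = 2) {
  plot_bad_precip <- plots$annual_precip < min_precip
  plot_bad_elev <- !plot_bad_precip & plots$elevation >= max_elev
  plot_keep <- !(plot_bad_precip | plot_bad_elev)

  excl_plots <- tibble::tibble(
    unit = "plot",
    id = plots$plot_id[!plot_keep],
    reason = as.character(ifelse(plot_bad_precip[!plot_keep], "precip",
                                 "elevation"))
  )
  plots_kept <- plots[plot_keep, , drop = FALSE]
  if (nrow(plots_kept) == 0) {
    abort("all plots excluded by precipitation/elevation filters; review config")
  }

  # monitoring span per plot (last minus first census date over all stems)
  span <- census |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(span = max(.data$date) - min(.data$date), .groups = "drop")
  plots_kept <- plots_kept |>
    dplyr::left_join(span, by = "plot_id") |>
    dplyr::mutate(demographic = !is.na(.data$span) & .data$span >= min_monitoring) |>
    dplyr::select(-"span")

  in_plot <- census$plot_id %in% plots_kept$plot_id
  no_genus <- in_plot & (is.na(census$genus) | !nzchar(trimws(census$genus)))
  keep <- in_plot & !no_genus

  excl_stems <- dplyr::bind_rows(
    tibble::tibble(unit = "stem_record",
                   id = census$stem_id[!in_plot],
                   reason = "plot_excluded"),
    tibble::tibble(unit = "stem_record",
                   id = census$stem_id[no_genus],
                   reason = "unidentified")
  )

  list(
    census = census[keep, , drop = FALSE],
    plots = plots_kept,
    exclusions = dplyr::bind_rows(excl_plots, excl_stems)
  )
}

#' Write a census tibble back to the documented CSV dialect
#'
#' Round-trip stable: `read_census(write_census(x, f))` reproduces `x`.
#'
#' @param census census tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  readr::write_csv(census[census_cols], path, progress = FALSE)
  invisible(path)
}
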