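# Diameter -> basal area / above-ground biomass conversions for trees and
# palms. Coefficients live in a parameter object rather than in code because
# they are transcribed from published allometries and users may substitute
# their own calibration.

#' Allometric coefficients for tree and palm biomass
#'
#' The tree equation is the pan-tropical diameter--wood-density--environment
#' model
#' \deqn{\ln AGB = c_0 + c_1 E + c_2 \ln \rho + c_3 \ln D + c_4 (\ln D)^2,}
#' with `D` in cm, wood density \eqn{\rho} in g cm\eqn{^{-3}}, `E` a
#' dimensionless bioclimatic stress covariate, and AGB in kg. The palm
#' equation is a diameter-only power law \eqn{\ln AGB = a + b \ln D}.
#'
#' @param tree_coefs numeric length-5: intercept, E coefficient, ln(wd)
#'   coefficient, ln(D) coefficient, (ln D)^2 coefficient.
#' @param palm_coefs numeric length-2: intercept `a` and slope `b` on ln(D),
#'   or `NULL` if palm biomass must not be computed.
#' @param provenance character note recording where the coefficients came
#'   from; kept alongside results for traceability.
#' @return an object of class `allometry_params`.
#' @examples
#' allometry_params()
#' @export
allometry_params <- function(
    tree_coefs = c(-1.803, -0.976, 0.976, 2.673, -0.0299),
    palm_coefs = c(-3.3488, 2.7483),
    provenance = paste(
      "tree: pan-tropical D/wd/E model (Chave et al. 2014, eq. 7);",
      "palm: Arecaceae family-level diameter model (Goodman et al. 2013)"
    )) {
  if (length(tree_coefs) != 5 || !all(is.finite(tree_coefs))) {
    abort("`tree_coefs` must be 5 finite numbers")
  }
  if (!is.null(palm_coefs) &&
      (length(palm_coefs) != 2 || !all(is.finite(palm_coefs)))) {
    abort("`palm_coefs` must be 2 finite numbers or NULL")
  }
  if (!nzchar(provenance)) abort("`provenance` must be non-empty")
  structure(
    list(tree_coefs = unname(tree_coefs),
         palm_coefs = if (is.null(palm_coefs)) NULL else unname(palm_coefs),
         provenance = provenance),
    class = "allometry_params"
  )
}

#' @export
print.allometry_params <- function(x, ...) {
  cat("<allometry_params>\n")
  cat("  tree: ln AGB =", paste(signif(x$tree_coefs, 5), collapse = ", "), "\n")
  if (is.null(x$palm_coefs)) {
    cat("  palm: unset\n")
  } else {
    cat("  palm: ln AGB =", paste(signif(x$palm_coefs, 5), collapse = ", "), "\n")
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Basal area from diameter
#'
#' @param d stem diameter in cm (measured at the point of measurement).
#' @return basal area in m^2: \eqn{\pi (D/200)^2}.
#' @examples
#' basal_area(20) # ~0.0314 m^2
#' @export
basal_area <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) abort("diameters must be positive")
  pi * (d / 200)^2
}

#' Tree above-ground biomass from diameter, wood density and E
#'
#' @param d diameter in cm.
#' @param wd wood density in g cm^-3.
#' @param e environmental-stress covariate E (dimensionless, plot-level).
#' @param params an [allometry_params()] object.
#' @return above-ground biomass in kg.
#' @examples
#' tree_agb(20, 0.6, 0)
#' @export
tree_agb <- function(d, wd, e, params = allometry_params()) {
  if (any(!is.finite(d)) || any(d <= 0)) abort("diameters must be positive")
  if (any(!is.finite(wd)) || any(wd <= 0)) abort("wood density must be positive")
  if (any(!is.finite(e))) abort("E must be finite")
  cf <- params$tree_coefs
  ld <- log(d)
  exp(cf[1] + cf[2] * e + cf[3] * log(wd) + cf[4] * ld + cf[5] * ld^2)
}

#' Palm above-ground biomass from diameter
#'
#' @inheritParams tree_agb
#' @return above-ground biomass in kg.
#' @examples
#' palm_agb(15)
#' @export
palm_agb <- function(d, params = allometry_params()) {
  if (is.null(params$palm_coefs)) {
    abort("palm coefficients unset; supply `palm_coefs` in allometry_params()")
  }
  if (any(!is.finite(d)) || any(d <= 0)) abort("diameters must be positive")
  cf <- params$palm_coefs
  exp(cf[1] + cf[2] * log(d))
}

# dispatch on growth form, vectorised; used by the trait derivations
stem_agb <- function(d, wd, e, growth_form, params = allometry_params()) {
  out <- numeric(length(d))
  palm <- growth_form == "palm"
  if (any(palm)) out[palm] <- palm_agb(d[palm], params)
  if (any(!palm)) out[!palm] <- tree_agb(d[!palm], wd[!palm], e[!palm], params)
  out
}
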