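#' Fixed numerical constants of the stability framework
#'
#' Collects the handful of fixed numbers shared by the viscosity-thickening and
#' depletion-flocculation halves of the model, with their conventional defaults.
#'
#' @param phi_c Critical packing fraction of hydrated polymer coils at which the
#'   solution viscosity diverges (dimensionless, default 0.57).
#' @param phi_star Effective volume fraction defining the critical viscosity
#'   concentration criterion (dimensionless, default 0.53). Note that exact
#'   inversion of the viscosity model at `eta_ratio_criterion = 100` gives
#'   0.513; 0.53 is the conventional value used for the simplified
#'   `21 * M / Rh^3` prefactor. Both routes are available (see
#'   [solve_phi_star()]).
#' @param eta_ratio_criterion Ratio of solution to solvent viscosity defining
#'   the CVC (dimensionless, default 100).
#' @param w_threshold Magnitude of the contact depletion attraction, in kT
#'   units, above which droplets flocculate (default 4).
#' @param wtpct_to_kgm3 Mass-concentration conversion factor, kg m^-3 per wt%
#'   (default 10, i.e. dilute aqueous solutions of density ~1000 kg m^-3).
#' @param avogadro Avogadro's number, mol^-1.
#'
#' @return An object of class `model_constants`.
#' @examples
#' model_constants()
#' model_constants(w_threshold = 6)
#' @export
model_constants <- function(phi_c = 0.57, phi_star = 0.53,
                            eta_ratio_criterion = 100, w_threshold = 4,
                            wtpct_to_kgm3 = 10, avogadro = 6.022e23) {
  x <- structure(
    list(phi_c = phi_c, phi_star = phi_star,
         eta_ratio_criterion = eta_ratio_criterion,
         w_threshold = w_threshold, wtpct_to_kgm3 = wtpct_to_kgm3,
         avogadro = avogadro),
    class = "model_constants")
  validate_model_constants(x)
}

validate_model_constants <- function(x) {
  stop_unless(is_scalar_num(x$phi_c) && x$phi_c > 0 && x$phi_c < 1,
              "phi_c must be in (0, 1)")
  stop_unless(is_scalar_num(x$phi_star) && x$phi_star > 0,
              "phi_star must be positive")
  stop_unless(x$phi_star < x$phi_c,
              "phi_star must be strictly less than phi_c")
  stop_unless(is_scalar_num(x$eta_ratio_criterion) && x$eta_ratio_criterion > 1,
              "eta_ratio_criterion must exceed 1")
  stop_unless(is_scalar_num(x$w_threshold) && x$w_threshold > 0,
              "w_threshold must be positive")
  stop_unless(is_scalar_num(x$wtpct_to_kgm3) && x$wtpct_to_kgm3 > 0,
              "wtpct_to_kgm3 must be positive")
  stop_unless(is_scalar_num(x$avogadro) && x$avogadro > 0,
              "avogadro must be positive")
  x
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Model constants:\n")
  cat(sprintf("  phi_c (packing fraction at divergence) : %g\n", x$phi_c))
  cat(sprintf("  phi_star (volume fraction at CVC)      : %g\n", x$phi_star))
  cat(sprintf("  eta ratio defining CVC                 : %g\n", x$eta_ratio_criterion))
  cat(sprintf("  |W| flocculation threshold (kT)        : %g\n", x$w_threshold))
  cat(sprintf("  wt%% -> kg m^-3 factor                  : %g\n", x$wtpct_to_kgm3))
  invisible(x)
}

#' Molecular description of one non-adsorbing polymer
#'
#' @param name Text label.
#' @param mw Weight-average molecular weight, kg mol^-1.
#' @param rh Weight-average hydrodynamic radius, nm.
#' @param purity Optional polysaccharide mass fraction in (0, 1].
#'
#' @return An object of class `polymer_spec`.
#' @examples
#' polymer_spec("guar_gum", mw = 2490, rh = 78)
#' @export
polymer_spec <- function(name, mw, rh, purity = NA_real_) {
  stop_unless(is.character(name) && length(name) == 1L && nzchar(name),
              "name must be a non-empty string")
  stop_unless(is_scalar_num(mw) && mw > 0, "mw must be a positive number (kg mol^-1)")
  stop_unless(is_scalar_num(rh) && rh > 0, "rh must be a positive number (nm)")
  if (!is.na(purity))
    stop_unless(is_scalar_num(purity) && purity > 0 && purity <= 1,
                "purity must lie in (0, 1]")
  structure(list(name = name, mw = as.numeric(mw), rh = as.numeric(rh),
                 purity = as.numeric(purity)),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("Polymer '%s': Mw = %g kg/mol, Rh = %g nm%s\n", x$name, x$mw, x$rh,
              if (is.na(x$purity)) "" else sprintf(", purity = %g", x$purity)))
  invisible(x)
}

#' A polymer at a given mass concentration
#'
#' @param polymer A [polymer_spec()].
#' @param concentration Mass concentration in wt% (>= 0). May be a vector.
#'
#' @return An object of class `solution_state`.
#' @export
solution_state <- function(polymer, concentration) {
  stop_unless(inherits(polymer, "polymer_spec"), "polymer must be a polymer_spec")
  stop_unless(is.numeric(concentration) && length(concentration) >= 1L &&
                all(is.finite(concentration)) && all(concentration >= 0),
              "concentration must be non-negative (wt%)")
  structure(list(polymer = polymer, concentration = as.numeric(concentration)),
            class = "solution_state")
}

#' Emulsion droplet population summary
#'
#' The depletion model needs only the droplet radius; the Sauter mean diameter
#' d32 (surface-weighted mean, \eqn{\sum d^3 / \sum d^2}) is the measured
#' summary it is derived from, with `droplet_radius = d32 / 2`.
#'
#' @param sauter_diameter Sauter mean diameter d32, in micrometres
#'   (default 2.0, the baseline whey-protein-stabilised sunflower-oil emulsion).
#' @param oil_fraction Oil mass fraction, informational only (default 0.064).
#'
#' @return An object of class `emulsion_spec` with fields `sauter_diameter`
#'   (um), `droplet_radius` (m) and `oil_fraction`.
#' @examples
#' emulsion_spec()                      # the 2.0 um baseline emulsion
#' emulsion_spec(sauter_diameter = 1.0)
#' @export
emulsion_spec <- function(sauter_diameter = 2.0, oil_fraction = 0.064) {
  stop_unless(is_scalar_num(sauter_diameter) && sauter_diameter > 0,
              "sauter_diameter must be positive (um)")
  stop_unless(is_scalar_num(oil_fraction) && oil_fraction >= 0 && oil_fraction < 1,
              "oil_fraction must lie in [0, 1)")
  structure(list(sauter_diameter = as.numeric(sauter_diameter),
                 droplet_radius = as.numeric(sauter_diameter) / 2 * 1e-6,
                 oil_fraction = as.numeric(oil_fraction)),
            class = "emulsion_spec")
}

#' @export
print.emulsion_spec <- function(x, ...) {
  cat(sprintf("Emulsion: d32 = %g um (droplet radius %g um), oil fraction %g\n",
              x$sauter_diameter, x$droplet_radius * 1e6, x$oil_fraction))
  invisible(x)
}

# internal helpers ---------------------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# coerce a polymer table row / polymer_spec / list of specs uniformly
as_polymer_list <- function(polymers) {
  if (inherits(polymers, "polymer_spec")) return(list(polymers))
  if (is.data.frame(polymers)) {
    stop_unless(all(c("name", "mw_kg_per_mol", "rh_nm") %in% names(polymers)),
                "polymer table must have columns name, mw_kg_per_mol, rh_nm")
    return(lapply(seq_len(nrow(polymers)), function(i) {
      purity <- if ("purity" %in% names(polymers)) polymers$purity[i] else NA_real_
      polymer_spec(polymers$name[i], polymers$mw_kg_per_mol[i],
                   polymers$rh_nm[i], purity)
    }))
  }
  if (is.list(polymers)) {
    stop_unless(all(vapply(polymers, inherits, logical(1), "polymer_spec")),
                "polymers must be polymer_spec objects")
    return(polymers)
  }
  stop("polymers must be a polymer_spec, a list of them, or a polymer table",
       call. = FALSE)
}
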