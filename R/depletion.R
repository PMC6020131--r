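#' Depletion attraction between droplets at contact
#'
#' Osmotic attraction between two emulsion droplets whose depletion zones
#' overlap at contact, for a non-adsorbing polymer treated as hard spheres of
#' the hydrodynamic radius:
#' \deqn{W/kT = -2\pi N_A R_h^2 \frac{c}{M}
#'   \left(1 + \frac{2\pi R_h^3 c N_A}{3M}\right)\left(R + \tfrac{2}{3}R_h\right)}
#' with all lengths in metres, c in kg m^-3 and M in kg mol^-1. All energies
#' are in kT units, so neither temperature nor Boltzmann's constant appears.
#' The potential is 0 with no depletant and strictly decreasing (more
#' attractive) in concentration, polymer size and droplet radius.
#'
#' @param sol A [solution_state()]; its concentration may be a vector (wt%).
#' @param emulsion An [emulsion_spec()].
#' @param constants A [model_constants()].
#' @return Contact potential(s) in kT units, `<= 0`.
#' @examples
#' guar <- polymer_spec("guar_gum", 2490, 78)
#' depletion_potential_contact(solution_state(guar, 0.0377), emulsion_spec())
#' @export
depletion_potential_contact <- function(sol, emulsion = emulsion_spec(),
                                        constants = model_constants()) {
  stop_unless(inherits(sol, "solution_state"), "sol must be a solution_state")
  stop_unless(inherits(emulsion, "emulsion_spec"), "emulsion must be an emulsion_spec")
  co <- depletion_coefficients(sol$polymer, emulsion, constants)
  c_kgm3 <- to_mass_concentration(sol$concentration, constants)
  co$quad_a * c_kgm3^2 + co$quad_b * c_kgm3
}

# W(c)/kT = quad_a c^2 + quad_b c with c in kg m^-3; both coefficients < 0.
# quad_b is the linear (dilute) coefficient -2 pi N_A Rh^2 (R + 2Rh/3)/M and
# quad_a = quad_b * 2 pi Rh^3 N_A / (3 M) carries the depletant osmotic
# non-ideality.
depletion_coefficients <- function(polymer, emulsion, constants) {
  rh <- polymer$rh * 1e-9
  r_drop <- emulsion$droplet_radius
  b <- -2 * pi * constants$avogadro * rh^2 * (r_drop + (2 / 3) * rh) / polymer$mw
  k_osm <- 2 * pi * rh^3 * constants$avogadro / (3 * polymer$mw)
  list(quad_a = b * k_osm, quad_b = b)
}

#' Critical flocculation concentration (CFC)
#'
#' Solves for the polymer concentration at which the contact depletion
#' attraction reaches the flocculation threshold (default 4 kT in magnitude):
#' with \eqn{W(c)/kT = a c^2 + b c} (see
#' [depletion_potential_contact()], a, b < 0), the CFC is the unique positive
#' root of \eqn{a c^2 + b c + w_{thr} = 0}, converted to wt%. The root is
#' verified by back-substitution into the potential to 1e-9 relative.
#'
#' @param polymer A [polymer_spec()].
#' @param emulsion An [emulsion_spec()].
#' @param constants A [model_constants()].
#' @return An object of class `depletion_result`: a list with `polymer`
#'   (name), `cfc` (wt%), `w_contact` (kT at the CFC, = -w_threshold),
#'   `quad_a`, `quad_b` (SI-concentration quadratic coefficients, both
#'   negative).
#' @examples
#' cfc(polymer_spec("guar_gum", 2490, 78), emulsion_spec())  # ~0.0377 wt%
#' @export
cfc <- function(polymer, emulsion = emulsion_spec(),
                constants = model_constants()) {
  stop_unless(inherits(polymer, "polymer_spec"), "polymer must be a polymer_spec")
  stop_unless(inherits(emulsion, "emulsion_spec"), "emulsion must be an emulsion_spec")
  co <- depletion_coefficients(polymer, emulsion, constants)
  a <- co$quad_a
  b <- co$quad_b
  w <- constants$w_threshold
  disc <- b^2 - 4 * a * w   # a < 0, w > 0 so disc > b^2 > 0 for physical inputs
  if (!is.finite(disc) || disc <= 0)
    stop(sprintf(
      "CFC solve failed: non-positive discriminant %g (a = %g, b = %g, w = %g)",
      disc, a, b, w), call. = FALSE)
  # unique positive root of a c^2 + b c + w = 0 (a, b < 0), written via the
  # root product to avoid cancellation when w is small relative to b^2
  c_kgm3 <- 2 * w / (-b + sqrt(disc))
  w_back <- a * c_kgm3^2 + b * c_kgm3
  if (abs(w_back + w) > 1e-9 * w)
    stop(sprintf("CFC back-substitution check failed: W(CFC) = %g, expected %g",
                 w_back, -w), call. = FALSE)
  structure(
    list(polymer = polymer$name,
         cfc = to_weight_percent(c_kgm3, constants),
         w_contact = w_back,
         quad_a = a, quad_b = b),
    class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("CFC of '%s': %.4g wt%% (contact potential %.4g kT)\n",
              x$polymer, x$cfc, x$w_contact))
  invisible(x)
}

#' Bisection solver for the CFC (independent test oracle)
#'
#' Finds the concentration at which the contact depletion attraction crosses
#' the flocculation threshold by bracketing (doubling an upper bound from
#' 0.001 wt%) followed by plain bisection to 1e-12 relative width. It shares
#' no algebra with the closed-form quadratic in [cfc()] beyond the potential
#' itself, and exists to cross-check it.
#'
#' @inheritParams cfc
#' @param tol Relative bracket-width termination tolerance.
#' @return The CFC in wt%.
#' @export
cfc_bisection <- function(polymer, emulsion = emulsion_spec(),
                          constants = model_constants(), tol = 1e-12) {
  stop_unless(inherits(polymer, "polymer_spec"), "polymer must be a polymer_spec")
  w <- constants$w_threshold
  f <- function(c_wtpct)
    depletion_potential_contact(solution_state(polymer, c_wtpct),
                                emulsion, constants) + w
  lo <- 0
  hi <- 1e-3
  n_double <- 0L
  while (f(hi) > 0) {
    lo <- hi
    hi <- 2 * hi
    n_double <- n_double + 1L
    if (n_double > 60L)
      stop("bisection oracle failed to bracket the CFC", call. = FALSE)
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * hi) break
  }
  (lo + hi) / 2
}
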