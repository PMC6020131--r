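#' Convert a mass concentration from wt% to kg per cubic metre
#'
#' The molecular equations take SI mass concentrations while laboratory
#' recipes are quoted in wt% (equivalently % w/v for dilute aqueous
#' solutions); the bridge is a single density-derived factor.
#'
#' @param c_wtpct Concentration(s) in wt%, >= 0.
#' @param constants A [model_constants()].
#' @return Concentration(s) in kg m^-3.
#' @examples
#' to_mass_concentration(0.11)  # 1.1 kg/m^3
#' @export
to_mass_concentration <- function(c_wtpct, constants = model_constants()) {
  stop_unless(is.numeric(c_wtpct) && all(is.finite(c_wtpct)),
              "c_wtpct must be numeric")
  stop_unless(all(c_wtpct >= 0), "concentration must be non-negative")
  c_wtpct * constants$wtpct_to_kgm3
}

#' @rdname to_mass_concentration
#' @param c_kgm3 Concentration(s) in kg m^-3, >= 0.
#' @export
to_weight_percent <- function(c_kgm3, constants = model_constants()) {
  stop_unless(is.numeric(c_kgm3) && all(is.finite(c_kgm3)),
              "c_kgm3 must be numeric")
  stop_unless(all(c_kgm3 >= 0), "concentration must be non-negative")
  c_kgm3 / constants$wtpct_to_kgm3
}

#' Effective volume fraction of hydrated polymer coils
#'
#' Treats each polymer molecule as a hard sphere of the hydrodynamic radius,
#' so the occupied fraction of solution volume is
#' \deqn{\phi_E = \frac{4}{3}\pi R_h^3 \frac{c N_A}{M}}
#' with \eqn{R_h} in metres, \eqn{c} in kg m^-3 and \eqn{M} in kg mol^-1.
#' \eqn{\phi_E} is exactly linear in concentration.
#'
#' @param sol A [solution_state()] (concentration may be a vector).
#' @param constants A [model_constants()].
#' @return Dimensionless effective volume fraction(s).
#' @examples
#' guar <- polymer_spec("guar_gum", 2490, 78)
#' effective_volume_fraction(solution_state(guar, 0.1))  # ~0.48
#' @export
effective_volume_fraction <- function(sol, constants = model_constants()) {
  stop_unless(inherits(sol, "solution_state"), "sol must be a solution_state")
  p <- sol$polymer
  c_kgm3 <- to_mass_concentration(sol$concentration, constants)
  rh_m <- p$rh * 1e-9
  (4 / 3) * pi * rh_m^3 * c_kgm3 * constants$avogadro / p$mw
}

#' Relative viscosity of a crowded polymer solution
#'
#' Hard-sphere crowding model for the viscosity of a polymer solution relative
#' to the solvent:
#' \deqn{\eta/\eta_1 = (1 - \phi_E/\phi_C)^{-2}}
#' which equals 1 in pure solvent and diverges as the effective volume
#' fraction approaches the critical packing fraction \eqn{\phi_C}.
#'
#' @param phi_e Effective volume fraction(s), in `[0, phi_c)`.
#' @param constants A [model_constants()].
#' @return Dimensionless viscosity ratio(s) eta/eta_1.
#' @examples
#' relative_viscosity(0)       # 1
#' relative_viscosity(0.285)   # 4
#' @export
relative_viscosity <- function(phi_e, constants = model_constants()) {
  stop_unless(is.numeric(phi_e) && all(is.finite(phi_e)), "phi_e must be numeric")
  stop_unless(all(phi_e >= 0), "phi_e must be non-negative")
  if (any(phi_e >= constants$phi_c))
    stop(sprintf(
      "viscosity diverges: phi_e (%g) has reached the critical packing fraction phi_c (%g)",
      max(phi_e), constants$phi_c), call. = FALSE)
  (1 - phi_e / constants$phi_c)^(-2)
}

#' Volume fraction at a given viscosity ratio
#'
#' Exact closed-form inverse of [relative_viscosity()]:
#' \eqn{\phi = \phi_C (1 - r^{-1/2})} for a viscosity ratio \eqn{r \ge 1}.
#' At the conventional CVC criterion r = 100 and \eqn{\phi_C = 0.57} this gives
#' 0.513; the conventional constant `phi_star = 0.53` used in the simplified
#' CVC prefactor is slightly larger (both are exposed deliberately).
#'
#' @param eta_ratio Viscosity ratio(s) >= 1.
#' @param phi_c Critical packing fraction (default 0.57).
#' @return Effective volume fraction(s) in `[0, phi_c)`.
#' @examples
#' solve_phi_star(100)  # 0.513
#' solve_phi_star(4)    # 0.285
#' @export
solve_phi_star <- function(eta_ratio, phi_c = 0.57) {
  stop_unless(is.numeric(eta_ratio) && all(is.finite(eta_ratio)),
              "eta_ratio must be numeric")
  if (any(eta_ratio < 1))
    stop("eta_ratio must be >= 1 (a polymer solution is at least as viscous as water)",
         call. = FALSE)
  stop_unless(is_scalar_num(phi_c) && phi_c > 0 && phi_c < 1, "phi_c must be in (0, 1)")
  phi_c * (1 - eta_ratio^(-1 / 2))
}

#' Critical viscosity concentration (CVC)
#'
#' Concentration at which the effective volume fraction reaches `phi_star`,
#' i.e. where the solution viscosity reaches the criterion multiple (by
#' default 100x) of the solvent viscosity:
#' \deqn{CVC = \frac{3 \phi^*_E M}{4 \pi R_h^3 N_A}}
#' converted to wt%. With the default constants this is numerically the
#' familiar desk rule `CVC (wt%) = 21 * M / Rh^3` for M in kg mol^-1 and Rh
#' in nm (see [cvc_prefactor()]).
#'
#' @param polymer A [polymer_spec()].
#' @param constants A [model_constants()].
#' @return CVC in wt%.
#' @examples
#' cvc(polymer_spec("guar_gum", 2490, 78))  # ~0.11 wt%
#' @export
cvc <- function(polymer, constants = model_constants()) {
  stop_unless(inherits(polymer, "polymer_spec"), "polymer must be a polymer_spec")
  rh_m <- polymer$rh * 1e-9
  c_kgm3 <- 3 * constants$phi_star * polymer$mw /
    (4 * pi * rh_m^3 * constants$avogadro)
  to_weight_percent(c_kgm3, constants)
}

#' Prefactor of the simplified CVC rule
#'
#' Derives the constant `A` in `CVC (wt%) = A * M / Rh^3` (M in kg mol^-1,
#' Rh in nm) from the full hard-sphere expression and the given constants.
#' With defaults A = 21.01, i.e. 21 to the nearest integer.
#'
#' @param constants A [model_constants()].
#' @return The dimensionless prefactor.
#' @export
cvc_prefactor <- function(constants = model_constants()) {
  # full formula at M = 1 kg/mol, Rh = 1 nm
  3 * constants$phi_star / (4 * pi * 1e-27 * constants$avogadro) /
    constants$wtpct_to_kgm3
}

#' Fit the hydrodynamic-radius vs molecular-weight power law
#'
#' Polymer families of a common chemistry follow \eqn{R_h = k M^{\nu}};
#' the fit is ordinary least squares on the log-log scale,
#' \eqn{\ln R_h = \ln k + \nu \ln M}.
#'
#' @param polymers A list of [polymer_spec()], or a polymer table
#'   (data.frame with `name`, `mw_kg_per_mol`, `rh_nm`). At least two
#'   polymers with distinct Mw are required.
#' @return An object of class `scaling_fit` with fields `k`
#'   (nm (kg/mol)^-nu), `nu`, `residual_se` (log-space), `se_log_k`, `se_nu`
#'   and `n`.
#' @examples
#' fit_rh_scaling(reference_polymer_table())
#' @export
fit_rh_scaling <- function(polymers) {
  ps <- as_polymer_list(polymers)
  if (length(ps) < 2L)
    stop("at least two polymers are needed to fit the Rh-Mw scaling", call. = FALSE)
  mw <- vapply(ps, `[[`, numeric(1), "mw")
  rh <- vapply(ps, `[[`, numeric(1), "rh")
  if (length(unique(mw)) < 2L)
    stop("polymers share a single Mw; the scaling exponent is unidentifiable",
         call. = FALSE)
  fit <- stats::lm(log(rh) ~ log(mw))
  # noiseless families fit perfectly; summary()'s warning about that is fine
  sm <- suppressWarnings(summary(fit))
  se <- if (length(ps) > 2L) sm$coefficients[, "Std. Error"] else c(0, 0)
  sigma <- if (length(ps) > 2L) sm$sigma else 0
  structure(
    list(k = unname(exp(stats::coef(fit)[1])),
         nu = unname(stats::coef(fit)[2]),
         residual_se = sigma,
         se_log_k = unname(se[1]), se_nu = unname(se[2]),
         n = length(ps)),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Rh = k * Mw^nu scaling fit (n = %d):\n", x$n))
  cat(sprintf("  k  = %.4g nm (kg/mol)^-nu (SE of log k: %.3g)\n", x$k, x$se_log_k))
  cat(sprintf("  nu = %.4g (SE %.3g); residual SE (log space) %.3g\n",
              x$nu, x$se_nu, x$residual_se))
  invisible(x)
}

#' Predict hydrodynamic radius from a scaling fit
#'
#' @param fit A `scaling_fit` from [fit_rh_scaling()].
#' @param mw Molecular weight(s), kg mol^-1.
#' @return Predicted Rh in nm.
#' @export
predict_rh <- function(fit, mw) {
  stop_unless(inherits(fit, "scaling_fit"), "fit must be a scaling_fit")
  stop_unless(is.numeric(mw) && all(mw > 0), "mw must be positive")
  fit$k * mw^fit$nu
}
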