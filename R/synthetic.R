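#' Generate a synthetic polymer family on an Rh-Mw power law
#'
#' Samples molecular weights log-uniformly over `mw_range` (so families spread
#' across decades, like real polysaccharide panels) and assigns hydrodynamic
#' radii from the power law `Rh = k * Mw^nu` with multiplicative lognormal
#' noise. Deterministic under a fixed seed.
#'
#' @param n Number of polymers (>= 1).
#' @param fit A `scaling_fit` (e.g. from [fit_rh_scaling()] on the packaged
#'   panel) supplying `k` and `nu`.
#' @param mw_range Length-2 increasing positive range of Mw, kg mol^-1.
#' @param noise_sd Standard deviation of the log-space Rh noise (default 0.05,
#'   i.e. ~5% multiplicative scatter).
#' @param seed Integer seed; the generator is reproducible under it.
#' @return A list of [polymer_spec()] named `syn_001`, `syn_002`, ...
#' @examples
#' fit <- fit_rh_scaling(reference_polymer_table())
#' fam <- generate_polymer_family(10, fit, seed = 1)
#' @export
generate_polymer_family <- function(n, fit, mw_range = c(200, 3000),
                                    noise_sd = 0.05, seed = 1L) {
  stop_unless(is_scalar_num(n) && n >= 1 && n == round(n), "n must be a positive count")
  stop_unless(inherits(fit, "scaling_fit"), "fit must be a scaling_fit")
  stop_unless(is.numeric(mw_range) && length(mw_range) == 2L &&
                all(mw_range > 0) && mw_range[1] < mw_range[2],
              "mw_range must be an increasing positive range")
  stop_unless(is_scalar_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(seed)
  mw <- exp(stats::runif(n, log(mw_range[1]), log(mw_range[2])))
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
  rh <- fit$k * mw^fit$nu * exp(eps)
  lapply(seq_len(n), function(i)
    polymer_spec(sprintf("syn_%03d", i), mw[i], rh[i]))
}

#' Generate a lognormal droplet population calibrated to a target d32
#'
#' Draws droplet diameters from a lognormal distribution whose log-scale sd
#' is `sigma_log` and whose log-location is set by the calibration rule
#' \deqn{\mu_{\log} = \ln(d_{32}^{target}) - 2.5\,\sigma_{\log}^2}
#' so that the analytic Sauter mean of the generating distribution,
#' \eqn{E d^3 / E d^2 = \exp(\mu_{\log} + 2.5 \sigma_{\log}^2)}, equals the
#' target exactly; the sample estimate then converges at the usual
#' \eqn{n^{-1/2}} rate. `sigma_log = 0` gives the degenerate monodisperse
#' population.
#'
#' @param n Number of droplets (>= 1).
#' @param sigma_log Log-space standard deviation (default 0.4, a unimodal
#'   right-tailed distribution typical of sonicated protein-stabilised
#'   emulsions).
#' @param target_d32 Target Sauter mean diameter, um (default 2.0).
#' @param seed Integer seed.
#' @return An object of class `droplet_population`: list with `diameters`
#'   (um), `seed`, `sigma_log`, `target_d32`, `mu_log`.
#' @examples
#' pop <- generate_droplet_population(1e4, seed = 1)
#' sauter_diameter(pop)  # ~2.0
#' @export
generate_droplet_population <- function(n, sigma_log = 0.4, target_d32 = 2.0,
                                        seed = 1L) {
  stop_unless(is_scalar_num(n) && n >= 1 && n == round(n), "n must be a positive count")
  stop_unless(is_scalar_num(sigma_log) && sigma_log >= 0, "sigma_log must be >= 0")
  stop_unless(is_scalar_num(target_d32) && target_d32 > 0, "target_d32 must be positive")
  mu_log <- log(target_d32) - 2.5 * sigma_log^2
  set.seed(seed)
  d <- if (sigma_log == 0) rep(target_d32, n) else
    stats::rlnorm(n, meanlog = mu_log, sdlog = sigma_log)
  structure(list(diameters = d, seed = seed, sigma_log = sigma_log,
                 target_d32 = target_d32, mu_log = mu_log),
            class = "droplet_population")
}

#' @export
print.droplet_population <- function(x, ...) {
  cat(sprintf(
    "Droplet population: n = %d, sigma_log = %g, target d32 = %g um (sample d32 = %.4g um)\n",
    length(x$diameters), x$sigma_log, x$target_d32, sauter_diameter(x)))
  invisible(x)
}

#' Sauter mean diameter of a droplet population
#'
#' Surface-weighted mean diameter \eqn{d_{32} = \sum d^3 / \sum d^2}, the
#' size summary laser-diffraction instruments report for emulsions.
#'
#' @param pop A `droplet_population` or a numeric vector of diameters (um).
#' @return The Sauter mean diameter in the units of the input.
#' @examples
#' sauter_diameter(c(1, 2))  # 1.8
#' @export
sauter_diameter <- function(pop) {
  d <- if (inherits(pop, "droplet_population")) pop$diameters else pop
  stop_unless(is.numeric(d) && length(d) >= 1L, "population must be non-empty")
  stop_unless(all(d > 0), "diameters must be positive")
  sum(d^3) / sum(d^2)
}

#' Oat-extract solution records
#'
#' The six fixed aqueous-extract records of the study design: water-soluble
#' extracts of oat bran, flour and flakes collected after 1 h and 72 h of
#' incubation, carrying the measured beta-glucan concentration of each
#' extract and the molecular weight of the beta-glucan extracted from that
#' material. Hydrodynamic radii default to the values measured for the oat
#' materials (`rh_source = "measured"`, imputed flag FALSE); alternatively
#' they can be imputed from an Rh-Mw scaling fit of the purified panel
#' (`rh_source = "scaling"`, imputed flag TRUE).
#'
#' @param rh_source `"measured"` or `"scaling"`.
#' @param fit A `scaling_fit`, required when `rh_source = "scaling"`;
#'   defaults to the fit of the packaged purified panel.
#' @return A data.frame with columns `source`, `incubation_h`,
#'   `c_extract_wtpct`, `mw_kg_per_mol`, `rh_nm`, `rh_imputed`.
#' @examples
#' oat_extract_fixtures()
#' oat_extract_fixtures(rh_source = "scaling")
#' @export
oat_extract_fixtures <- function(rh_source = c("measured", "scaling"),
                                 fit = NULL) {
  rh_source <- match.arg(rh_source)
  x <- data.frame(
    source = rep(c("bran", "flour", "flakes"), each = 2L),
    incubation_h = rep(c(1, 72), times = 3L),
    c_extract_wtpct = c(0.27, 0.54, 0.26, 0.57, 0.10, 0.51),
    mw_kg_per_mol = rep(c(2100, 1740, 1680), each = 2L),
    rh_measured_nm = rep(c(78, 70, 70), each = 2L),
    stringsAsFactors = FALSE)
  if (rh_source == "measured") {
    x$rh_nm <- x$rh_measured_nm
    x$rh_imputed <- FALSE
  } else {
    if (is.null(fit)) fit <- fit_rh_scaling(reference_polymer_table())
    x$rh_nm <- predict_rh(fit, x$mw_kg_per_mol)
    x$rh_imputed <- TRUE
  }
  x$rh_measured_nm <- NULL
  x
}
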