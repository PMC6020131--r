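# the purified panel used throughout: guar gum plus three beta-glucan
# fractions of decreasing size
panel <- list(
  guar = polymer_spec("guar_gum", 2490, 78, 0.871),
  bg1  = polymer_spec("BG1", 1020, 51, 0.901),
  bg2  = polymer_spec("BG2", 650, 38, 0.910),
  bg3  = polymer_spec("BG3", 272, 23, 0.938))

baseline_emulsion <- emulsion_spec(sauter_diameter = 2.0, oil_fraction = 0.064)
defaults <- model_constants()

# direct evaluation of the contact depletion potential, written independently
# of the package's coefficient bookkeeping (the tests' own oracle)
oracle_w_contact <- function(mw, rh_nm, c_wtpct, r_drop_m = 1e-6,
                             n_avo = 6.022e23) {
  rh <- rh_nm * 1e-9
  c_si <- c_wtpct * 10
  -2 * pi * n_avo * rh^2 * (c_si / mw) *
    (1 + 2 * pi * rh^3 * c_si * n_avo / (3 * mw)) *
    (r_drop_m + (2 / 3) * rh)
}

random_physical_polymer <- function() {
  mw <- exp(stats::runif(1, log(50), log(5000)))
  rh <- 1.04 * mw^0.55 * exp(stats::rnorm(1, 0, 0.2))
  polymer_spec("rand", mw, rh)
}
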